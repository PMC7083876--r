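Package: msatABC
Title: Coalescent Simulation and Approximate Bayesian Computation for
    Microsatellite Bottleneck Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Demographic reconstruction for diploid microsatellite data from
    heavily exploited populations. Provides a single-population coalescent
    simulator for unlinked microsatellite loci under piecewise-constant
    demography with a generalized stepwise mutation model; per-locus diversity
    statistics (observed and unbiased expected heterozygosity, rarefied
    allelic richness, Garza-Williamson M-ratio, Fis, private alleles,
    Weir-Cockerham pairwise Fst with bootstrap confidence intervals); the
    Cornuet-Luikart heterozygosity-excess bottleneck test under a two-phase
    mutation model; rejection-based approximate Bayesian computation for
    model selection between bottleneck and constant-size demographies with
    leave-one-out cross-validation, posterior predictive checks and a
    goodness-of-fit test; and simulation of the expected proportional loss of
    allelic diversity under bottlenecks of varying strength and duration.
    Includes a synthetic multi-population data generator and GENEPOP, CSV and
    STRUCTURE file interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    rlang,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    ggplot2
Config/testthat/edition: 3
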