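# msatABC

Demographic reconstruction from diploid microsatellite genotypes for
populations with a suspected recent collapse — the typical conservation-
genetics setting of a species hunted to near-extinction one to four
centuries ago. The package answers two linked questions:

1. **Did a bottleneck happen, and how severe was it?** Via the
   Cornuet–Luikart heterozygosity-excess test and rejection-based
   approximate Bayesian computation (ABC) comparing a three-epoch
   bottleneck demography against a matched constant-size demography.
2. **How much allelic diversity did it cost?** Via paired coalescent
   simulation of bottleneck and constant-size scenarios across a grid of
   bottleneck strengths and durations.

## The models

Everything rests on a single-population neutral coalescent for unlinked
microsatellite loci under a piecewise-constant demography: *k* lineages
coalesce at rate C(k,2)/(2·Nₑ(t)), with time in generations and diploid
sizes. The bottleneck model has epochs (0, Nₑ), (t_bot_end, Nₑ_bot),
(t_bot_start, Nₑ_hist); the non-bottleneck model lacks the middle epoch.
Mutations are Poisson on branches with a generalized stepwise law:
P(|S| = s) = (1 − p)·p^(s−1), so p is the proportion of multistep
mutations (the TPM80 preset of the bottleneck-test literature is also
provided). ABC compares observed and simulated datasets through three
across-locus summaries — mean allele count, proportion of alleles under 5%
frequency, and the Garza–Williamson M-ratio M = k/(range + 1) — retaining
the closest fraction of simulations under MAD-scaled Euclidean distance.
Cross-validated prediction error is
E_pred = Σᵢ(θ̄ᵢ − θᵢ)²/(n·Var(θ)); values below 1 mean the posterior is
informative.

## Worked example

Simulate a population that passed a ten-generation bottleneck of effective
size 200 ending ten generations ago (historical size 10,000), then test for
the bottleneck and price its diversity loss:

```r
library(msatABC)

d <- simulate_dataset(181, 39, bottleneck_model(10000, 200, 10000, 10, 20),
                      mutation_model(9e-5, p_multistep = 0.2), seed = 42)
round(abc_summary_vector(d), 3)
#>        mean_k prop_low_freq        mean_M
#>         6.667         0.338         0.887

het_excess_test(d, n_iter = 500, seed = 43)
#> Heterozygosity-excess test: 31/39 loci in excess (prop = 0.795)
#>   sign test p = 0.005883
#>   standardized differences p = 0.0002474
#>   Wilcoxon signed-rank p = 9.462e-05

loss <- expected_allele_loss(10000, 200, 10, n_sims = 2000, seed = 44)
sprintf("loss = %.3f (SE %.4f)", loss$loss, loss$se)
#> [1] "loss = 0.136 (SE 0.0067)"
```

Reading: the depressed M-ratio (0.887 vs ≈ 0.95 for equilibrium data) and
the significant excess of heterozygosity relative to equilibrium
expectations at the observed allele counts are the two classic bottleneck
signatures; yet the same bottleneck removes only ≈ 14% of alleles — severe
demographic collapse, modest genetic cost.

The full chain (diversity table, pairwise Fst, per-population bottleneck
tests, ABC model choice and Nₑ_bot posteriors, loss scenarios) runs as one
pipeline over a GENEPOP/CSV file or the built-in synthetic preset:

```r
run_full_analysis(run_config(input = "fur_seal", seed = 1), "out/")
```

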