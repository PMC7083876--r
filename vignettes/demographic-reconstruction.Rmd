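---
title: "Reconstructing exploitation bottlenecks from microsatellite data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing exploitation bottlenecks from microsatellite data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

msatABC asks a question that recurs across conservation genetics: a species
was hunted to the brink a century or two ago, its census numbers collapsed by
orders of magnitude — how much of that demographic catastrophe is written in
its genes, and how much genetic diversity did it actually lose? The package
implements, as reusable and tested components, the full simulation-based
inference chain needed to answer it from diploid microsatellite genotypes:
a coalescent simulator, classical diversity statistics, the
heterozygosity-excess bottleneck test, rejection-based approximate Bayesian
computation (ABC) over competing demographic models, and direct simulation of
the expected loss of allelic diversity.

```{r setup}
library(msatABC)
```

## The coalescent simulator

The engine underneath every analysis is a single-population, neutral,
continuous-time coalescent for unlinked microsatellite loci under a
piecewise-constant demography. Time runs backwards in generations; with `k`
ancestral lineages and diploid effective size $N_e(t)$, the next coalescence
occurs at rate $\binom{k}{2} / (2 N_e(t))$. Epoch boundaries are handled by
time rescaling, which is exact for exponential waiting times. Two model
shapes cover the hypotheses under test:

* a **bottleneck model** with three epochs: present size $N_e$, a reduced
  size $N_{e\mathrm{bot}}$ between $t_{\mathrm{bot\,end}}$ and
  $t_{\mathrm{bot\,start}}$ generations ago, and a historical size
  $N_{e\mathrm{hist}}$ before that;
* a **non-bottleneck model**, identical except that the bottleneck epoch is
  absent.

```{r}
bottleneck_model(10000, 200, 10000, t_bot_end = 10, t_bot_start = 20)
```

Mutations fall on branches as a Poisson process with rate $\mu$ per locus per
generation and perturb the allele size (in repeat units) by a signed step.
The generalized stepwise model (GSM) draws step magnitudes from a geometric
law $P(|S| = s) = (1 - p)\,p^{s-1}$, so the parameter $p$ *is* the proportion
of multistep mutations. The two-phase preset `tpm80()` (80% single-step,
multistep magnitude with variance 30) reproduces the conventions of the
classical bottleneck-testing literature. Two deliberate simplifications are
worth knowing about:

* **No allele-size range constraint.** Real microsatellites may saturate;
  the simulator lets the ladder grow freely. All statistics remain
  translation-invariant, and the M-ratio stays computable. A consequence
  observed in our cross-validation experiments is that the mean allele count
  retains more information about very large historical population sizes than
  a range-constrained simulator would.
* **The root allele is fixed at 50 repeats and gene copies are paired
  sequentially into diploids.** Both choices are invisible to every
  statistic in the package (tested), because the statistics are
  translation-invariant and the sample is exchangeable under random mating.

The simulator is validated in the test suite against closed forms —
$E[T_2] = 2N_e$, $E[T_{\mathrm{MRCA}}] = 4N_e(1 - 1/n)$, the
piecewise-exponential distribution of $T_2$ across an epoch change, and the
Ohta–Kimura stepwise-model heterozygosity
$H_e = 1 - 1/\sqrt{1 + 8 N_e \mu}$ — and against an independent
discrete-generation Wright–Fisher genealogy simulator at small $N_e$.

## Diversity statistics

`per_locus_diversity()`, `rarefied_allelic_richness()`, `m_ratio()`,
`prop_low_freq_alleles()`, `private_alleles()` and `pairwise_fst()` cover the
standard per-locus and per-population table of a range-wide microsatellite
survey. Conventions, where more than one exists in the literature:

* expected heterozygosity is Nei's unbiased estimator
  $\frac{n}{n-1}(1 - \sum_i p_i^2)$ over $n$ gene copies;
* $F_{is} = 1 - H_o / H_e$ per locus (0 where $H_e = 0$), averaged over loci;
* allelic richness uses exact hypergeometric rarefaction to `g` gene copies
  (20 by default, i.e. ten diploids);
* the "low-frequency" cutoff is strict ($p < 0.05$);
* pairwise $F_{st}$ is Weir & Cockerham's $\theta$, summed over variance
  components across loci and alleles, with percentile bootstrap CIs over
  loci;
* missing gene copies are dropped locus-wise and frequencies renormalised.

```{r}
d <- simulate_dataset(60, 10, bottleneck_model(10000, 200, 10000, 10, 20),
                      mutation_model(9e-5, p_multistep = 0.2), seed = 1)
head(per_locus_diversity(d), 3)
```

## The heterozygosity-excess test

A recent bottleneck removes rare alleles faster than it removes
heterozygosity, so for a short transient the observed $H_e$ exceeds the
equilibrium $H_e$ of a population with the same allele count. The test
therefore needs, for every locus, the distribution of equilibrium $H_e$
conditional on the observed allele count $k$ and sample size.
`equilibrium_het_distribution()` reconstructs it by simulation: the scaled
mutation rate $\theta$ is tuned by bisection until the mean simulated allele
count matches $k$, then replicates are rejection-filtered to exactly $k$
alleles (the conditioning scheme of the original program is unpublished;
this is the natural reconstruction). Three dataset-level significance tests
are reported: an exact sign test using the Poisson-binomial distribution of
the number of excess loci (each locus has its own null excess probability),
the standardized-differences test
$T_2 = \sum_l (\Delta H_l / \sigma_l) / \sqrt{L}$ against a standard normal,
and a one-tailed Wilcoxon signed-rank test. Monomorphic loci are excluded
from all three.

Calibration, verified in the tests: on data simulated *at equilibrium under
the same mutation model*, the sign and standardized-differences tests
reject at rates inside the binomial band at $\alpha = 0.05$; on data
simulated through an $N_{e\mathrm{bot}} = 200$, ten-generation bottleneck,
power exceeds 80%. Two caveats that are properties of the method rather
than the implementation:

* the one-tailed Wilcoxon on mean-centred $\Delta H$ is intrinsically
  anticonservative, because the conditional null distribution of $H_e$
  given the allele count is left-skewed — more than half its mass lies
  above its mean, so the median of $\Delta H$ is positive under the null,
  and the effect strengthens with the number of loci. The sign test
  absorbs the same skew correctly through its per-locus null excess
  probabilities, which is why we recommend reading the sign and
  standardized-differences tests as the calibrated pair and the Wilcoxon
  as a descriptive companion;
* the test is sensitive to the *assumed* step law: evaluating
  near-single-step data under TPM80's large multistep variance shifts it
  toward spurious excess. The pipeline therefore exposes the assumed model
  (`het_model` in `run_config()`), and negative controls should match it
  to the generating process.

## Rejection ABC

`build_reference_table()` draws parameters from the priors, simulates a
dataset per draw (matching the observed sample size), and stores three
across-locus summary statistics: mean allele count, proportion of alleles
below 5% frequency, and mean M-ratio. `abc_reject()` retains the fraction
`tolerance` of rows closest to the observed summaries in Euclidean distance,
each statistic scaled by its median absolute deviation across the table (the
conventional rejection-ABC scaling; SD is the fallback for degenerate MADs).
Model choice (`model_posterior()`, `cv_model_selection()`), parameter
estimation with leave-one-out cross-validation
(`cv_parameter_estimation()`), posterior predictive checks and a
goodness-of-fit test complete the chain. Cross-validated prediction error is
$E_{pred} = \sum_i(\bar\theta_i - \theta_i)^2 / (n\,\mathrm{Var}(\theta))$;
the printed formula in the source literature omits the $1/n$, but its stated
interpretation (an uninformative estimator scores $\approx 1$) forces the
conventional variance normalisation, which is what we implement. The point
estimate $\bar\theta_i$ is the posterior median — a robust choice the
source leaves unstated.

Two prior presets are shipped because the source specification is internally
inconsistent: the **literal** log-normal for current and historical sizes
(log-mean 10.5, log-sd 1, median ≈ 36,300) and a **verbal** preset matching
the accompanying description of "~90% of draws between 3,000 and 15,000"
(median 6,708, log-sd 0.489). The literal preset is the default everywhere.
In our cross-validation experiments the literal prior reproduces the
published model-selection rates more closely, while the verbal prior
reproduces the published parameter prediction errors more closely — neither
is a clean winner, and we do not silently pick one; see `abc_priors()`.

Default problem sizes are chosen for desk-scale reproducibility: reference
tables of $2\times10^4$ to $10^5$ simulations with tolerances of $10^{-2}$
to $5\times10^{-3}$ (a few hundred accepted draws) rather than the
$2\times10^7$-simulation, $5\times10^{-4}$-tolerance production scale, which
remains available simply by passing larger numbers. At the reduced scale,
correct-classification rates and prediction errors carry Monte-Carlo noise
of a few percentage points.

## Expected loss of allelic diversity

`expected_allele_loss()` quantifies what a bottleneck of a given strength
and duration *costs*: matched pairs of datasets are simulated under the
three-epoch bottleneck model and under a constant-size model at the
historical size, with $\mu$ and the multistep parameter drawn from the ABC
priors per replicate pair (the same draw for both members, which leaves the
ratio-of-means estimator unchanged and reduces noise), and the loss is
$1 - \bar k_{\mathrm{bot}} / \bar k_{\mathrm{const}}$ with a delta-method
standard error. The loss is defined on mean allele counts rather than
heterozygosity deliberately — rare alleles are lost preferentially but carry
little heterozygosity, so `expected_het_loss()` under the same scenario is
always smaller (tested). `loss_scenarios()` sweeps historical sizes
(1,000 / 10,000 / 50,000 by default) and `loss_grid()` maps bottleneck size
(25–600) against duration (1–20 generations) with the bottleneck end fixed
ten generations ago. For the three-scenario runs the bottleneck is placed at
10–20 generations ago; at microsatellite mutation rates, moving the end time
within 1–20 generations changes the result by less than the Monte-Carlo
error, so the grid's fixed end time is adopted throughout.

## The synthetic multi-population generator

`generate_multipop_dataset()` exists so that the whole pipeline can be
exercised without any external data. It emulates a set of relict
populations: one ancestral allele pool per locus is drawn from the
equilibrium coalescent at the historical size, each population then drifts
through its own bottleneck generations by Wright–Fisher multinomial
resampling of the pool frequencies, and admixed populations draw each gene
copy from a source population according to mixing proportions. The
`fur_seal_config()` preset uses five populations (sample sizes 197, 1042,
396, 184, 181), 39 loci, bottlenecks of $N_{e\mathrm{bot}} = 200$ for ten
generations ending ten generations ago on an ancestral size of 10,000, and
a mutation model (rate $9\times10^{-5}$, 20% multistep) calibrated once to
give heterozygosities near 0.7 and M-ratios near 0.8.

What this emulation is and is not: between-population differentiation arises
solely from independent drift out of a shared pool — it is not a joint
multi-population coalescent, carries no migration, and its site-frequency
details differ from a true two-population history. The ancestral pool must
stay much larger than any sample (20,000 gene copies by default): resampling
a small pool truncates the rare-allele tail and mimics a bottleneck
signature, which we observed directly when validating the negative control.
Tests that pass on these synthetic data demonstrate internal consistency of
the inference chain, not correctness on any particular real population.

## The pipeline

`run_full_analysis()` chains every stage — diversity table, pairwise
$F_{st}$, per-population heterozygosity-excess tests, ABC model selection
and $N_{e\mathrm{bot}}$ posteriors, loss scenarios — writing per-stage CSV
reports and a machine-readable `summary.json`, each stamped with the seed
and a hash of the configuration. Every stage derives its own seed
deterministically from the global seed and the stage name, so re-running a
configuration reproduces the summary exactly. Populations larger than the
ABC target size are subsampled (seeded) so that observed and simulated
summaries refer to the same sample size — a mismatch there biases model
choice toward the bottleneck model, which is why the reference table is
always simulated at the target size. A YAML interface (`read_run_config()`)
and a thin Rscript wrapper (`inst/scripts/run_analysis.R`) serve shell use.

## Numerical and degenerate-input conventions

* All stochastic functions take an explicit seed; unseeded calls continue
  the session RNG stream.
* `equilibrium_het_distribution()` errors (naming the locus context) if the
  conditioning cannot accumulate its replicates within `200 * n_iter`
  attempts; $k = 1$ returns a flagged degenerate result.
* Rejection with `tolerance = 1` returns the prior sample; the accepted
  count is always `round(tolerance * n)` with a floor of one row.
* Zero-MAD summary statistics fall back to SD scaling with a warning.
* Monomorphic loci: excluded from the heterozygosity-excess tests, `M = 1`,
  $H_o = H_e = F_{is} = 0$, rarefied richness 1.
* Populations with fewer than two scored individuals are dropped from
  $F_{st}$ with a warning.

## Known limitations

* Single-population coalescent only; the ABC cannot represent migration or
  admixture, and the admixed synthetic population is deliberately outside
  its model space.
* The unbounded allele ladder means very large $\theta$ produces unbounded
  allele ranges; with the priors shipped this is harmless, but user-supplied
  priors far outside them should be sanity-checked against the M-ratio's
  behaviour.
* The heterozygosity-excess conditioning reconstructs an unpublished
  algorithm; per-locus p-values match the published tool qualitatively
  (significance patterns), not digit-for-digit.
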