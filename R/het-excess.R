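#' Null distribution of equilibrium heterozygosity given an allele count
#'
#' Simulates single loci at mutation-drift equilibrium (constant-size
#' coalescent) under the given stepwise mutation model and conditions on the
#' observed allele count `k`: the scaled mutation rate theta is first tuned
#' by bisection so the mean simulated allele count matches `k`, then
#' replicates are rejection-filtered to exactly `k` alleles. The retained
#' unbiased expected heterozygosities form the equilibrium reference
#' distribution of the heterozygosity-excess bottleneck test.
#'
#' @param n_copies Number of gene copies in the sample.
#' @param k_alleles Observed allele count to condition on (`1 <= k <= n`).
#' @param mut A [mutation_model]; only its step law is used (theta is tuned).
#' @param n_iter Number of conditioned replicates to retain (default 1000).
#' @param seed Optional integer seed.
#' @param max_attempts Cap on total simulated replicates before giving up.
#' @return List with `mean`, `sd`, `he` (the retained values), `prob_excess`
#'   (fraction of retained values above their mean; the per-locus null
#'   probability of heterozygosity excess), `theta` and `degenerate`.
#' @examples
#' eq <- equilibrium_het_distribution(50, 5, tpm80(), n_iter = 200, seed = 1)
#' eq$mean
#' @export
equilibrium_het_distribution <- function(n_copies, k_alleles, mut = tpm80(),
                                         n_iter = 1000, seed = NULL,
                                         max_attempts = 200 * n_iter) {
  if (k_alleles < 1 || k_alleles > n_copies) {
    stop("k_alleles must be in [1, n_copies]")
  }
  if (!is.null(seed)) set.seed(seed)
  if (k_alleles == 1) {
    return(list(mean = 0, sd = 0, he = numeric(0), prob_excess = 0,
                theta = 0, degenerate = TRUE))
  }
  theta <- tune_theta(n_copies, k_alleles, mut)
  he <- numeric(0)
  attempts <- 0
  chunk <- max(500L, n_iter)
  while (length(he) < n_iter) {
    if (attempts >= max_attempts) {
      stop(sprintf(
        "could not accumulate %d equilibrium replicates with k = %d (n = %d)",
        n_iter, k_alleles, n_copies))
    }
    m <- .cpp_equilibrium_k_he(n_copies, chunk, theta, mut$p_multistep,
                               mut$q_multi)
    attempts <- attempts + chunk
    he <- c(he, m[m[, 1] == k_alleles, 2])
  }
  he <- he[seq_len(n_iter)]
  mn <- mean(he)
  list(mean = mn, sd = stats::sd(he), he = he,
       prob_excess = mean(he > mn), theta = theta, degenerate = FALSE)
}

# Bisection on log(theta) so that the mean simulated allele count at
# equilibrium matches the target k.
tune_theta <- function(n_copies, k_target, mut, n_probe = 200, iters = 14) {
  mean_k <- function(theta) {
    mean(.cpp_equilibrium_k_he(n_copies, n_probe, theta, mut$p_multistep,
                               mut$q_multi)[, 1])
  }
  lo <- 0.01
  hi <- 2
  while (mean_k(hi) < k_target && hi < 5000) hi <- hi * 2.5
  for (i in seq_len(iters)) {
    mid <- sqrt(lo * hi)
    if (mean_k(mid) < k_target) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

# Exact Poisson-binomial upper tail P(X >= x) by dynamic programming.
poisson_binomial_tail <- function(p, x) {
  dp <- c(1, rep(0, length(p)))
  for (pi in p) {
    dp <- c(dp[1] * (1 - pi),
            dp[-1] * (1 - pi) + dp[-length(dp)] * pi)
  }
  sum(dp[(x + 1):length(dp)])
}

#' Heterozygosity-excess bottleneck test
#'
#' For each polymorphic locus, compares the observed unbiased expected
#' heterozygosity with the equilibrium distribution conditioned on the
#' observed allele count (see [equilibrium_het_distribution]). Recently
#' bottlenecked populations show a transient excess because rare alleles are
#' lost faster than heterozygosity declines. Three dataset-level tests are
#' reported, all one-tailed for excess:
#' \itemize{
#'   \item sign test: exact Poisson-binomial tail probability of observing at
#'     least the seen number of excess loci, given the per-locus null excess
#'     probabilities;
#'   \item standardized differences test: `T2 = sum(DH_l / sd_l) / sqrt(L)`
#'     against a standard normal;
#'   \item one-tailed Wilcoxon signed-rank test on the `DH` values.
#' }
#'
#' The conditional null of `He` given the allele count is left-skewed, so
#' the Wilcoxon member of the trio runs anticonservative on equilibrium
#' data (its null median of `DH` is positive); the sign test, whose
#' per-locus null excess probabilities absorb the skew, and the
#' standardized-differences test are the calibrated pair.
#'
#' @param d A single-population [genotype_data] object.
#' @param mut A [mutation_model] (default the TPM80 preset).
#' @param n_iter Equilibrium replicates per locus (default 1000).
#' @param seed Optional integer seed.
#' @param null_cache Optional environment from [new_het_null_cache()] to
#'   reuse equilibrium null distributions across datasets that share sample
#'   sizes and allele counts.
#' @return An object of class `het_excess_result`: list with `per_locus`
#'   data.frame (k, He_obs, He_eq_mean, He_eq_sd, DH, std_DH, excess),
#'   `prop_het_exc`, `n_loci_excess`, `n_loci_used`, `p_sign`, `p_std_diff`,
#'   `p_wilcoxon`.
#' @export
het_excess_test <- function(d, mut = tpm80(), n_iter = 1000, seed = NULL,
                            null_cache = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(null_cache)) null_cache <- new_het_null_cache()
  L <- n_loci(d)
  per <- data.frame(locus = d$loci, n_copies = NA_real_, k = NA_real_,
                    He_obs = NA_real_, He_eq_mean = NA_real_,
                    He_eq_sd = NA_real_, DH = NA_real_, std_DH = NA_real_,
                    excess = NA, p_null_excess = NA_real_)
  for (l in seq_len(L)) {
    copies <- locus_copies(d, l)
    n <- length(copies)
    if (n == 0) next
    p <- tabulate(factor(copies)) / n
    k <- length(p)
    per$n_copies[l] <- n
    per$k[l] <- k
    per$He_obs[l] <- n / (n - 1) * (1 - sum(p^2))
    if (k < 2) next  # monomorphic loci are excluded from the tests
    key <- sprintf("n%d_k%d_p%g_q%g_i%d", n, k, mut$p_multistep, mut$q_multi,
                   n_iter)
    if (is.null(null_cache[[key]])) {
      null_cache[[key]] <- equilibrium_het_distribution(n, k, mut,
                                                        n_iter = n_iter)
    }
    eq <- null_cache[[key]]
    per$He_eq_mean[l] <- eq$mean
    per$He_eq_sd[l] <- eq$sd
    per$DH[l] <- per$He_obs[l] - eq$mean
    per$std_DH[l] <- if (eq$sd > 0) per$DH[l] / eq$sd else NA_real_
    per$excess[l] <- per$DH[l] > 0
    per$p_null_excess[l] <- eq$prob_excess
  }
  used <- which(!is.na(per$DH))
  if (length(used) == 0) stop("all loci are monomorphic or empty")
  if (length(used) < 10) {
    warning("fewer than 10 polymorphic loci; test power will be low")
  }
  n_exc <- sum(per$excess[used])
  t2 <- sum(per$std_DH[used]) / sqrt(length(used))
  res <- list(
    per_locus = per,
    n_loci_used = length(used),
    n_loci_excess = n_exc,
    prop_het_exc = n_exc / length(used),
    p_sign = poisson_binomial_tail(per$p_null_excess[used], n_exc),
    p_std_diff = stats::pnorm(t2, lower.tail = FALSE),
    p_wilcoxon = stats::wilcox.test(per$DH[used], alternative = "greater",
                                    exact = FALSE, correct = TRUE)$p.value
  )
  class(res) <- "het_excess_result"
  res
}

#' @rdname het_excess_test
#' @export
new_het_null_cache <- function() new.env(parent = emptyenv())

#' @export
print.het_excess_result <- function(x, ...) {
  cat(sprintf(
    "Heterozygosity-excess test: %d/%d loci in excess (prop = %.3f)\n",
    x$n_loci_excess, x$n_loci_used, x$prop_het_exc))
  cat(sprintf("  sign test p = %.4g\n", x$p_sign))
  cat(sprintf("  standardized differences p = %.4g\n", x$p_std_diff))
  cat(sprintf("  Wilcoxon signed-rank p = %.4g\n", x$p_wilcoxon))
  invisible(x)
}
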