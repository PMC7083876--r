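#' Per-locus diversity statistics
#'
#' Computes, for every locus (pooling all individuals in `d`): the number of
#' non-missing gene copies, allele count `k`, observed heterozygosity `Ho`
#' (fraction of heterozygous individuals among those with both copies
#' scored), Nei's unbiased expected heterozygosity
#' `He = n/(n-1) * (1 - sum(p^2))`, the inbreeding coefficient
#' `Fis = 1 - Ho/He` (0 where `He = 0`), and the Garza-Williamson M-ratio.
#' Loci with no data are flagged and excluded from the dataset-level means.
#'
#' @param d A [genotype_data] object.
#' @return A data.frame of class `diversity_table`, one row per locus, with a
#'   `"means"` attribute holding locus-averaged values.
#' @examples
#' a <- array(c(10L, 10L, 11L, 10L), dim = c(2, 1, 2))
#' per_locus_diversity(genotype_data(a, "p"))
#' @export
per_locus_diversity <- function(d) {
  L <- n_loci(d)
  out <- data.frame(locus = d$loci, n_copies = NA_real_, k = NA_real_,
                    Ho = NA_real_, He = NA_real_, Fis = NA_real_,
                    M_ratio = NA_real_, excluded = FALSE)
  for (l in seq_len(L)) {
    copies <- locus_copies(d, l)
    if (length(copies) == 0) {
      out$excluded[l] <- TRUE
      next
    }
    n <- length(copies)
    p <- tabulate(factor(copies)) / n
    out$n_copies[l] <- n
    out$k[l] <- length(p)
    g1 <- d$alleles[, l, 1]
    g2 <- d$alleles[, l, 2]
    ok <- !is.na(g1) & !is.na(g2)
    out$Ho[l] <- if (any(ok)) mean(g1[ok] != g2[ok]) else 0
    he <- if (n > 1) n / (n - 1) * (1 - sum(p^2)) else 0
    out$He[l] <- he
    out$Fis[l] <- if (he > 0) 1 - out$Ho[l] / he else 0
    out$M_ratio[l] <- length(p) / (max(copies) - min(copies) + 1)
  }
  keep <- !out$excluded
  attr(out, "means") <- colMeans(out[keep, c("k", "Ho", "He", "Fis", "M_ratio")])
  class(out) <- c("diversity_table", "data.frame")
  out
}

#' Rarefied allelic richness
#'
#' Expected number of alleles in a random subsample of `g` gene copies,
#' computed exactly by the hypergeometric rarefaction formula
#' `A_r = sum_i (1 - choose(N - N_i, g) / choose(N, g))` over alleles `i`
#' with `N_i` copies out of `N` at the locus.
#'
#' @param d A [genotype_data] object.
#' @param g Rarefaction size in gene copies (e.g. 20 for ten diploids).
#' @return Named numeric vector of per-locus values with a `"mean"` attribute.
#' @examples
#' a <- array(c(10L, 10L, 10L, 11L), dim = c(2, 1, 2))
#' rarefied_allelic_richness(genotype_data(a, "p"), g = 2)
#' @export
rarefied_allelic_richness <- function(d, g) {
  g <- as.integer(g)
  if (g < 1) stop("g must be >= 1")
  vals <- vapply(seq_len(n_loci(d)), function(l) {
    copies <- locus_copies(d, l)
    N <- length(copies)
    if (g > N) {
      stop(sprintf("locus %s has only %d gene copies (< g = %d)",
                   d$loci[l], N, g))
    }
    Ni <- tabulate(factor(copies))
    sum(1 - exp(lchoose(N - Ni, g) - lchoose(N, g)))
  }, numeric(1))
  names(vals) <- d$loci
  attr(vals, "mean") <- mean(vals)
  vals
}

#' Garza-Williamson M-ratio
#'
#' `M = k / (r + 1)` per locus, where `k` is the allele count and `r` the
#' allele size range in repeat units. Bottlenecks depress M because lost
#' alleles leave vacant rungs in the size ladder.
#'
#' @param d A [genotype_data] object; allele sizes must be integer repeat
#'   counts (divide by `repeat_unit` first if they are in base pairs).
#' @param repeat_unit Optional per-locus motif length used to convert sizes
#'   to repeat units; conversion must be exact.
#' @return Named per-locus vector with a `"mean"` attribute.
#' @export
m_ratio <- function(d, repeat_unit = NULL) {
  vals <- vapply(seq_len(n_loci(d)), function(l) {
    copies <- locus_copies(d, l)
    if (length(copies) == 0) return(NA_real_)
    if (!is.null(repeat_unit)) {
      u <- repeat_unit[min(l, length(repeat_unit))]
      if (any(copies %% u != 0)) {
        stop(sprintf("locus %s: allele sizes are not multiples of %d",
                     d$loci[l], u))
      }
      copies <- copies %/% u
    }
    length(unique(copies)) / (max(copies) - min(copies) + 1)
  }, numeric(1))
  names(vals) <- d$loci
  attr(vals, "mean") <- mean(vals, na.rm = TRUE)
  vals
}

#' Proportion of low-frequency alleles
#'
#' Per locus, the fraction of alleles whose sample frequency is strictly
#' below `threshold`; returned per locus with the across-locus mean.
#'
#' @param d A [genotype_data] object.
#' @param threshold Frequency cutoff (default 0.05; strict inequality).
#' @return Named per-locus vector with a `"mean"` attribute.
#' @export
prop_low_freq_alleles <- function(d, threshold = 0.05) {
  vals <- vapply(seq_len(n_loci(d)), function(l) {
    copies <- locus_copies(d, l)
    if (length(copies) == 0) return(NA_real_)
    f <- tabulate(factor(copies)) / length(copies)
    mean(f < threshold)
  }, numeric(1))
  names(vals) <- d$loci
  attr(vals, "mean") <- mean(vals, na.rm = TRUE)
  vals
}

#' Private alleles per population
#'
#' Number of alleles observed in exactly one population, summed across loci.
#'
#' @param d A [genotype_data] object with at least two populations.
#' @return Named integer vector, one count per population.
#' @export
private_alleles <- function(d) {
  pops <- levels(d$pop)
  if (length(pops) < 2) stop("private alleles require >= 2 populations")
  counts <- stats::setNames(integer(length(pops)), pops)
  for (l in seq_len(n_loci(d))) {
    sets <- lapply(pops, function(p) unique(locus_copies(d, l, p)))
    all_alleles <- unlist(sets)
    tab <- table(all_alleles)
    priv <- names(tab)[tab == 1]
    for (i in seq_along(pops)) {
      counts[i] <- counts[i] + sum(sets[[i]] %in% as.integer(priv))
    }
  }
  counts
}

# Weir & Cockerham (1984) variance components for one locus across r
# populations. Returns c(a, b, c) summed over alleles.
wc_components <- function(d, l, pops) {
  r <- length(pops)
  g1 <- d$alleles[, l, 1]
  g2 <- d$alleles[, l, 2]
  ok <- !is.na(g1) & !is.na(g2)
  n_i <- p_i <- h_i <- NULL
  alleles <- sort(unique(c(g1[ok], g2[ok])))
  n_i <- vapply(pops, function(p) sum(ok & d$pop == p), numeric(1))
  if (any(n_i < 1)) return(c(0, 0, 0))
  abc <- c(0, 0, 0)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  for (al in alleles) {
    p_i <- vapply(pops, function(p) {
      idx <- ok & d$pop == p
      (sum(g1[idx] == al) + sum(g2[idx] == al)) / (2 * sum(idx))
    }, numeric(1))
    h_i <- vapply(pops, function(p) {
      idx <- ok & d$pop == p
      mean((g1[idx] == al) != (g2[idx] == al))
    }, numeric(1))
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    abc <- abc + c(a, b, cc)
  }
  abc
}

#' Pairwise Weir-Cockerham Fst
#'
#' Multilocus Weir & Cockerham (1984) theta for every pair of populations:
#' the ratio of summed among-population variance components to summed total
#' components across loci and alleles. Optional percentile bootstrap
#' confidence intervals are obtained by resampling loci.
#'
#' @param d A [genotype_data] object with >= 2 populations; populations with
#'   fewer than 2 scored individuals are dropped with a warning.
#' @param n_boot Number of bootstrap resamples over loci (0 = no CIs).
#' @param conf Confidence level for the percentile interval.
#' @param seed Optional integer seed for the bootstrap.
#' @return A symmetric matrix of class `fst_matrix` with 0 on the diagonal;
#'   when `n_boot > 0`, attributes `lower` and `upper` hold the CI matrices.
#' @export
pairwise_fst <- function(d, n_boot = 0, conf = 0.95, seed = NULL) {
  pops <- levels(d$pop)
  sizes <- table(d$pop)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning("dropping populations with < 2 individuals: ",
            paste(small, collapse = ", "))
    pops <- setdiff(pops, small)
  }
  if (length(pops) < 2) stop("need >= 2 populations with >= 2 individuals")
  if (!is.null(seed)) set.seed(seed)
  L <- n_loci(d)
  np <- length(pops)
  fst <- matrix(0, np, np, dimnames = list(pops, pops))
  lower <- upper <- fst
  for (i in seq_len(np - 1)) {
    for (j in seq((i + 1), np)) {
      comps <- vapply(seq_len(L), function(l) wc_components(d, l, pops[c(i, j)]),
                      numeric(3))
      theta <- function(idx) {
        s <- rowSums(comps[, idx, drop = FALSE])
        if (sum(s) == 0) 0 else s[1] / sum(s)
      }
      fst[i, j] <- fst[j, i] <- theta(seq_len(L))
      if (n_boot > 0) {
        bs <- replicate(n_boot, theta(sample.int(L, L, replace = TRUE)))
        qs <- stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2))
        lower[i, j] <- lower[j, i] <- qs[1]
        upper[i, j] <- upper[j, i] <- qs[2]
      }
    }
  }
  if (n_boot > 0) {
    attr(fst, "lower") <- lower
    attr(fst, "upper") <- upper
  }
  class(fst) <- c("fst_matrix", class(fst))
  fst
}

#' ABC summary-statistic vector
#'
#' The three across-locus means used as rejection-ABC summaries: mean allele
#' count per locus (raw counts, since simulated and observed samples are the
#' same size), mean proportion of alleles at frequency below 5\%, and mean
#' M-ratio.
#'
#' @param d A single-population [genotype_data] object (subset first if
#'   needed).
#' @return Named numeric vector `(mean_k, prop_low_freq, mean_M)`.
#' @export
abc_summary_vector <- function(d) {
  pld <- per_locus_diversity(d)
  m <- attr(pld, "means")
  c(mean_k = unname(m["k"]),
    prop_low_freq = unname(attr(prop_low_freq_alleles(d), "mean")),
    mean_M = unname(m["M_ratio"]))
}

#' Distribution of a statistic over random individual subsamples
#'
#' Repeatedly draws `n_ind` individuals without replacement and evaluates
#' `statistic` on the subsample; used to compare populations of unequal
#' sample size on an equal footing.
#'
#' @param d A [genotype_data] object.
#' @param statistic Function taking a [genotype_data] and returning a scalar.
#' @param n_ind Subsample size in individuals (default 10).
#' @param n_rep Number of subsamples (default 1000).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n_rep`.
#' @export
subsample_statistic <- function(d, statistic, n_ind = 10, n_rep = 1000,
                                seed = NULL) {
  n <- n_individuals(d)
  if (n_ind > n) stop("n_ind exceeds the number of individuals")
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n_rep), function(r) {
    idx <- sample.int(n, n_ind)
    sub <- genotype_data(d$alleles[idx, , , drop = FALSE], d$pop[idx],
                         loci = d$loci, repeat_bp = d$repeat_bp)
    statistic(sub)
  }, numeric(1))
}

#' Per-population diversity summary table
#'
#' A report with one row per population: sample size, rarefied allelic
#' richness (mean and SD over loci), observed heterozygosity, M-ratio, Fis
#' and private alleles — the standard multi-population diversity table.
#'
#' @param d A [genotype_data] object.
#' @param rarefaction_g Rarefaction size in gene copies (default 20, i.e.
#'   ten diploid individuals).
#' @return A data.frame, one row per population.
#' @export
diversity_summary <- function(d, rarefaction_g = 20) {
  pops <- levels(d$pop)
  priv <- if (length(pops) >= 2) private_alleles(d) else
    stats::setNames(rep(NA_integer_, length(pops)), pops)
  rows <- lapply(pops, function(p) {
    sub <- subset_pops(d, p)
    pld <- per_locus_diversity(sub)
    ar <- rarefied_allelic_richness(sub, rarefaction_g)
    data.frame(population = p, n = n_individuals(sub),
               Ar = mean(ar), Ar_sd = stats::sd(ar),
               Ho = mean(pld$Ho, na.rm = TRUE),
               Ho_sd = stats::sd(pld$Ho, na.rm = TRUE),
               M_ratio = mean(pld$M_ratio, na.rm = TRUE),
               M_ratio_sd = stats::sd(pld$M_ratio, na.rm = TRUE),
               Fis = mean(pld$Fis, na.rm = TRUE),
               Fis_sd = stats::sd(pld$Fis, na.rm = TRUE),
               private_alleles = priv[p])
  })
  do.call(rbind, rows)
}

#' Write a diversity table or Fst matrix to CSV
#'
#' Reports are stamped with the package version and the RNG seed used to
#' produce them in a leading comment line.
#'
#' @param x A data.frame or matrix.
#' @param path Output path.
#' @param seed Seed recorded in the header.
#' @export
write_report_csv <- function(x, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(report_header(seed), con)
  if (is.matrix(x)) {
    utils::write.csv(as.data.frame(unclass(x)), con, row.names = TRUE)
  } else {
    utils::write.csv(x, con, row.names = FALSE)
  }
  invisible(path)
}
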