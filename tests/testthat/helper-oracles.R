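# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Discrete-generation backward Wright-Fisher genealogy at 2N gene copies:
# every generation each lineage picks a parent slot uniformly; lineages
# sharing a slot merge (multiple mergers are chained into binary nodes at the
# same generation). Returns an object mutate_genealogy() accepts.
wf_genealogy <- function(n, two_N) {
  parent <- rep(NA_integer_, 2 * n - 1)
  time <- numeric(2 * n - 1)
  active <- seq_len(n)
  nxt <- n + 1L
  t <- 0
  while (length(active) > 1) {
    t <- t + 1
    slot <- sample.int(two_N, length(active), replace = TRUE)
    for (s in unique(slot[duplicated(slot)])) {
      ids <- which(slot == s)
      while (length(ids) > 1) {
        a <- active[ids[1]]
        b <- active[ids[2]]
        parent[c(a, b)] <- nxt
        time[nxt] <- t
        active[ids[1]] <- nxt
        active <- active[-ids[2]]
        slot <- slot[-ids[2]]
        nxt <- nxt + 1L
        ids <- which(slot == s)
      }
    }
  }
  structure(list(parent = parent, time = time, n_tips = n),
            class = "genealogy")
}

# Brute-force rarefaction: mean number of distinct alleles over all
# g-subsets of the gene copies.
rarefaction_enum <- function(copies, g) {
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2, function(idx) length(unique(copies[idx]))))
}

# Independently coded single-locus Weir-Cockerham (1984) theta for two
# populations given as lists of diploid genotypes (2-column matrices).
wc_theta_oracle <- function(geno1, geno2) {
  genos <- list(geno1, geno2)
  r <- 2
  n_i <- vapply(genos, nrow, numeric(1))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  alleles <- unique(c(geno1, geno2))
  num <- den <- 0
  for (al in alleles) {
    p_i <- vapply(genos, function(g) mean(g == al), numeric(1))
    h_i <- vapply(genos, function(g) mean((g[, 1] == al) != (g[, 2] == al)),
                  numeric(1))
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Convenience: genotype_data from a list of per-locus 2-column genotype
# matrices (one population) or from explicit allele arrays.
toy_dataset <- function(locus_genotypes, pop = "p1") {
  n <- nrow(locus_genotypes[[1]])
  L <- length(locus_genotypes)
  arr <- array(NA_integer_, dim = c(n, L, 2))
  for (l in seq_len(L)) {
    arr[, l, 1] <- as.integer(locus_genotypes[[l]][, 1])
    arr[, l, 2] <- as.integer(locus_genotypes[[l]][, 2])
  }
  genotype_data(arr, pop)
}

# A synthetic two-model reference table with prescribed summary-statistic
# generators; used to test the ABC machinery without running the simulator.
fake_reference_table <- function(n_per_model, gen_bot, gen_con, seed = 1) {
  set.seed(seed)
  bot <- gen_bot(n_per_model)
  con <- gen_con(n_per_model)
  tab <- rbind(
    data.frame(model = "bottleneck", bot),
    data.frame(model = "non_bottleneck", con)
  )
  attr(tab, "n_ind") <- 181
  attr(tab, "n_loci") <- 39
  class(tab) <- c("reference_table", "data.frame")
  tab
}
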