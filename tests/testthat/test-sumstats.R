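test_that("per-locus heterozygosity, Fis and M-ratio match hand computation", {
  # genotypes (10,11) and (10,10): Ho = 1/2; plug-in He = 1 - 10/16 = 0.375,
  # unbiased = 4/3 * 0.375 = 0.5; Fis = 0
  d <- toy_dataset(list(cbind(c(10, 10), c(11, 10))))
  pld <- per_locus_diversity(d)
  expect_equal(pld$Ho, 0.5)
  expect_equal(pld$He, 0.5)
  expect_equal(pld$Fis, 0)
  expect_equal(pld$k, 2)

  mono <- toy_dataset(list(cbind(c(7, 7), c(7, 7))))
  pm <- per_locus_diversity(mono)
  expect_equal(pm$Ho, 0)
  expect_equal(pm$He, 0)
  expect_equal(pm$Fis, 0)
  expect_equal(pm$M_ratio, 1)
})

test_that("unbiased He dominates the plug-in estimate", {
  set.seed(21)
  d <- simulate_dataset(15, 20, constant_model(500, 500, 10),
                        mutation_model(1e-3))
  pld <- per_locus_diversity(d)
  plugin <- vapply(seq_len(n_loci(d)), function(l) {
    a <- as.vector(d$alleles[, l, ])
    1 - sum((tabulate(factor(a)) / length(a))^2)
  }, numeric(1))
  expect_true(all(pld$He >= plugin - 1e-12))
  expect_true(all((pld$He == 0) == (pld$k == 1)))
})

test_that("rarefied allelic richness equals brute-force enumeration", {
  # copies {A, A, B} at g = 2: subsamples {AA, AB, AB} -> (1 + 2 + 2)/3
  d <- toy_dataset(list(cbind(c(10, 10), c(10, 11))))
  # individual copies: 10,10,10,11
  expect_equal(as.numeric(rarefied_allelic_richness(d, 2)),
               rarefaction_enum(c(10, 10, 10, 11), 2))
  set.seed(22)
  for (i in 1:5) {
    copies <- sample(1:4, 8, replace = TRUE) + 9L
    arr <- array(copies, dim = c(4, 1, 2))
    dd <- genotype_data(arr, "p")
    for (g in c(2, 5, 8)) {
      expect_equal(as.numeric(rarefied_allelic_richness(dd, g)),
                   rarefaction_enum(as.vector(arr), g), tolerance = 1e-10)
    }
    # monotone in g; equals k at g = N
    ar <- vapply(2:8, function(g) as.numeric(rarefied_allelic_richness(dd, g)),
                 numeric(1))
    expect_true(all(diff(ar) >= -1e-12))
    expect_equal(ar[length(ar)], length(unique(copies)))
  }
  expect_error(rarefied_allelic_richness(d, 5), "gene copies")
})

test_that("M-ratio counts vacant rungs in the allele-size ladder", {
  d <- toy_dataset(list(cbind(c(10, 12), c(13, 10))))  # {10, 12, 13}
  expect_equal(as.numeric(m_ratio(d)), 3 / 4)
  ladder <- toy_dataset(list(cbind(c(10, 11), c(12, 10))))
  expect_equal(as.numeric(m_ratio(ladder)), 1)
  # base-pair sizes with a dinucleotide motif
  bp <- toy_dataset(list(cbind(c(20, 24), c(26, 20))))
  expect_equal(as.numeric(m_ratio(bp, repeat_unit = 2)), 3 / 4)
  odd <- toy_dataset(list(cbind(c(20, 25), c(26, 20))))
  expect_error(m_ratio(odd, repeat_unit = 2), "multiples")
})

test_that("low-frequency allele proportion uses a strict 5% cutoff", {
  # 50 copies split 45/3/2: frequencies 0.90, 0.06, 0.04 -> 1 of 3 below 5%
  copies <- c(rep(10, 45), rep(11, 3), rep(12, 2))
  arr <- array(copies, dim = c(25, 1, 2))
  d <- genotype_data(arr, "p")
  expect_equal(as.numeric(prop_low_freq_alleles(d)), 1 / 3)
  eq <- genotype_data(array(c(10, 11), dim = c(10, 1, 2)), "p")
  expect_equal(as.numeric(prop_low_freq_alleles(eq)), 0)
  # 100 singleton copies: every allele is below 5%
  singles <- genotype_data(array(101:200, dim = c(50, 1, 2)), "p")
  expect_equal(as.numeric(prop_low_freq_alleles(singles)), 1)
})

test_that("private alleles are counted per population", {
  arr <- array(NA_integer_, dim = c(4, 1, 2))
  arr[, 1, 1] <- c(10L, 10L, 11L, 11L)
  arr[, 1, 2] <- c(11L, 11L, 12L, 12L)   # pop1 {10,11}, pop2 {11,12}
  d <- genotype_data(arr, c("p1", "p1", "p2", "p2"))
  expect_equal(private_alleles(d), c(p1 = 1L, p2 = 1L))
  same <- genotype_data(array(rep(c(10L, 11L), each = 4), dim = c(4, 1, 2)),
                        c("p1", "p1", "p2", "p2"))
  expect_equal(unname(private_alleles(same)), c(0L, 0L))
  disj <- array(NA_integer_, dim = c(4, 1, 2))
  disj[, 1, 1] <- c(10L, 11L, 20L, 21L)
  disj[, 1, 2] <- c(12L, 10L, 20L, 21L)   # pop1 {10,11,12}, pop2 {20,21}
  dd <- genotype_data(disj, c("p1", "p1", "p2", "p2"))
  expect_equal(private_alleles(dd), c(p1 = 3L, p2 = 2L))
  expect_error(private_alleles(toy_dataset(list(cbind(1:2, 1:2)))), "popul")
})

test_that("pairwise Fst matches an independent Weir-Cockerham evaluation", {
  set.seed(23)
  g1 <- cbind(sample(10:13, 12, TRUE), sample(10:13, 12, TRUE))
  g2 <- cbind(sample(11:15, 8, TRUE), sample(11:15, 8, TRUE))
  arr <- array(NA_integer_, dim = c(20, 1, 2))
  arr[1:12, 1, ] <- g1
  arr[13:20, 1, ] <- g2
  d <- genotype_data(arr, rep(c("a", "b"), c(12, 8)))
  expect_equal(unname(pairwise_fst(d)["a", "b"]), wc_theta_oracle(g1, g2),
               tolerance = 1e-12)
})

test_that("Fst hits the boundary cases and bootstrap CIs bracket it", {
  fixed <- array(NA_integer_, dim = c(8, 3, 2))
  fixed[1:4, , ] <- 10L
  fixed[5:8, , ] <- 20L
  dfix <- genotype_data(fixed, rep(c("a", "b"), each = 4))
  expect_equal(unname(pairwise_fst(dfix)["a", "b"]), 1)

  set.seed(24)
  pool <- simulate_dataset(60, 12, constant_model(2000, 2000, 10),
                           mutation_model(5e-4))
  dpan <- genotype_data(pool$alleles, rep(c("a", "b"), each = 30))
  f <- pairwise_fst(dpan, n_boot = 200, seed = 25)
  expect_lt(abs(f["a", "b"]), 0.05)
  expect_true(attr(f, "lower")["a", "b"] <= f["a", "b"])
  expect_true(attr(f, "upper")["a", "b"] >= f["a", "b"])
  expect_equal(diag(f), c(a = 0, b = 0))

  tiny <- genotype_data(pool$alleles[1:5, , , drop = FALSE],
                        c("a", "a", "a", "a", "b"))
  expect_warning(expect_error(pairwise_fst(tiny), ">= 2"), "dropping")
})

test_that("statistics are invariant to translation and reordering", {
  set.seed(26)
  d <- simulate_dataset(25, 6, constant_model(1000, 1000, 10),
                        mutation_model(5e-4))
  sv <- abc_summary_vector(d)
  shifted <- genotype_data(d$alleles + 7L, d$pop, loci = d$loci)
  expect_equal(abc_summary_vector(shifted), sv)
  perm_i <- sample(25)
  perm_l <- sample(6)
  perm <- genotype_data(d$alleles[perm_i, perm_l, , drop = FALSE],
                        d$pop[perm_i], loci = d$loci[perm_l])
  expect_equal(unname(abc_summary_vector(perm)), unname(sv))
  expect_equal(sort(rarefied_allelic_richness(perm, 10)),
               sort(rarefied_allelic_richness(d, 10)), ignore_attr = TRUE)
})

test_that("the ABC summary vector collapses correctly for degenerate data", {
  mono <- toy_dataset(list(cbind(c(7, 7), c(7, 7))))
  expect_equal(unname(abc_summary_vector(mono)), c(1, 0, 1))
})

test_that("subsampling reproduces rarefaction in expectation", {
  mono <- toy_dataset(list(cbind(rep(7, 12), rep(7, 12))))
  ar1 <- subsample_statistic(mono, function(s)
    as.numeric(rarefied_allelic_richness(s, 2)), n_ind = 3, n_rep = 20, seed = 1)
  expect_true(all(ar1 == 1))

  set.seed(27)
  d <- simulate_dataset(30, 4, constant_model(1000, 1000, 10),
                        mutation_model(5e-4))
  full <- subsample_statistic(d, function(s) mean(per_locus_diversity(s)$k),
                              n_ind = 30, n_rep = 1, seed = 2)
  expect_equal(full, mean(per_locus_diversity(d)$k))
  # mean subsampled allele count = exact rarefaction at g = 2 * n_ind
  ks <- subsample_statistic(d, function(s) mean(per_locus_diversity(s)$k),
                            n_ind = 5, n_rep = 4000, seed = 3)
  expect_equal(mean(ks), attr(rarefied_allelic_richness(d, 10), "mean"),
               tolerance = 0.02)
  expect_error(subsample_statistic(d, mean, n_ind = 31), "exceeds")
})

test_that("the per-population summary table has the standard columns", {
  set.seed(28)
  arr <- array(sample(10:14, 2 * 24 * 3, TRUE), dim = c(24, 3, 2))
  d <- genotype_data(arr, rep(c("a", "b"), each = 12))
  tab <- diversity_summary(d, rarefaction_g = 10)
  expect_equal(tab$population, c("a", "b"))
  expect_true(all(c("n", "Ar", "Ho", "M_ratio", "Fis", "private_alleles")
                  %in% names(tab)))
  expect_equal(tab$n, c(12, 12))
})
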