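cm1000 <- constant_model(1000, 1000, 50)

test_that("degenerate genealogies behave", {
  g <- simulate_genealogy(1, cm1000, seed = 1)
  expect_equal(g$n_tips, 1)
  expect_equal(total_branch_length(g), 0)
  expect_equal(tmrca(g), 0)
  expect_error(simulate_genealogy(0, cm1000), "n_lineages")
})

test_that("coalescence times match analytic expectations", {
  set.seed(101)
  t2 <- replicate(30000, tmrca(simulate_genealogy(2, cm1000)))
  # E[T2] = 2 Ne
  expect_lt(abs(mean(t2) - 2000), 4 * sd(t2) / sqrt(length(t2)))
  tm <- replicate(10000, tmrca(simulate_genealogy(10, cm1000)))
  # E[TMRCA] = 4 Ne (1 - 1/n)
  expect_lt(abs(mean(tm) - 3600), 4 * sd(tm) / sqrt(length(tm)))
})

test_that("epoch changes rescale the coalescent clock exactly", {
  set.seed(102)
  dm <- demographic_model(c(0, 500), c(1000, 200))
  t2 <- replicate(20000, tmrca(simulate_genealogy(2, dm)))
  # piecewise-exponential survival: rate 1/2000 before 500, then 1/400
  cdf <- function(t) {
    ifelse(t < 500, 1 - exp(-t / 2000),
           1 - exp(-500 / 2000) * exp(-(t - 500) / 400))
  }
  ks <- suppressWarnings(stats::ks.test(t2, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("genealogies are binary, ultrametric and convertible to phylo", {
  g <- simulate_genealogy(25, cm1000, seed = 7)
  expect_equal(sum(is.na(g$parent)), 1)          # single root
  expect_true(all(g$time[seq_len(g$n_tips)] == 0))
  kids <- tabulate(g$parent[!is.na(g$parent)], nbins = 2 * g$n_tips - 1)
  expect_true(all(kids[-seq_len(g$n_tips)] == 2))  # internal nodes binary
  internal <- g$time[-seq_len(g$n_tips)]
  expect_true(all(diff(internal) > 0))           # merge times increase
  ph <- genealogy_to_phylo(g)
  expect_s3_class(ph, "phylo")
  expect_true(ape::is.ultrametric(ph, tol = 1e-8))
  expect_equal(max(ape::node.depth.edgelength(ph)), tmrca(g))
})

test_that("mutation process follows the stepwise law", {
  g <- simulate_genealogy(10, cm1000, seed = 3)
  expect_true(all(mutate_genealogy(g, mutation_model(0)) == 50))
  # single branch of length 1e4 at mu = 1e-4: mutation count is Poisson(1);
  # under the +-1 SMM the squared displacement has the same mean
  branch <- structure(list(parent = c(3L, 3L, NA), time = c(0, 0, 1e4),
                           n_tips = 2L), class = "genealogy")
  set.seed(104)
  disp <- replicate(20000, mutate_genealogy(branch, mutation_model(1e-4))[1] - 50)
  expect_lt(abs(mean(disp^2) - 1), 4 * sd(disp^2) / sqrt(length(disp)))
  expect_error(mutation_model(-1e-4), "non-negative")
})

test_that("equilibrium heterozygosity matches the Ohta-Kimura closed form", {
  # SMM at theta = 4 Ne mu = 2: He = 1 - 1/sqrt(1 + 2 theta) = 0.5528
  set.seed(105)
  dm <- constant_model(10000, 10000, 50)
  he <- unlist(lapply(1:20, function(i) {
    d <- simulate_dataset(50, 40, dm, mutation_model(5e-5))
    per_locus_diversity(d)$He
  }))
  expected <- 1 - 1 / sqrt(1 + 8 * 10000 * 5e-5)
  expect_lt(abs(mean(he) - expected), 4 * sd(he) / sqrt(length(he)))
})

test_that("simulated datasets have the requested shape and no missing data", {
  d <- simulate_dataset(181, 39, cm1000, mutation_model(1e-4), seed = 9)
  expect_equal(dim(d$alleles), c(181, 39, 2))
  expect_false(anyNA(d$alleles))
  mono <- simulate_dataset(10, 5, cm1000, mutation_model(0), seed = 9)
  expect_true(all(mono$alleles == 50))
})

test_that("identical seeds give identical datasets; root allele is invisible", {
  d1 <- simulate_dataset(30, 8, cm1000, mutation_model(2e-4), seed = 11)
  d2 <- simulate_dataset(30, 8, cm1000, mutation_model(2e-4), seed = 11)
  expect_identical(d1$alleles, d2$alleles)
  d3 <- simulate_dataset(30, 8, cm1000, mutation_model(2e-4),
                         root_allele = 120L, seed = 11)
  expect_equal(d3$alleles - d1$alleles, array(70L, dim = dim(d1$alleles)),
               ignore_attr = TRUE)
  expect_equal(abc_summary_vector(d3), abc_summary_vector(d1))
})

test_that("a three-epoch model with equal sizes equals the constant model", {
  flat3 <- bottleneck_model(1000, 1000, 1000, 10, 20)
  set.seed(12)
  k3 <- replicate(300, mean(per_locus_diversity(
    simulate_dataset(20, 5, flat3, mutation_model(5e-4)))$k))
  set.seed(13)
  k2 <- replicate(300, mean(per_locus_diversity(
    simulate_dataset(20, 5, cm1000, mutation_model(5e-4)))$k))
  expect_gt(stats::wilcox.test(k3, k2)$p.value, 0.01)
})

test_that("coalescent agrees with a discrete Wright-Fisher oracle", {
  # Ne = 100, n = 10 copies, theta = 1: compare mean allele count and He
  set.seed(106)
  mut <- mutation_model(2.5e-3)
  n_rep <- 3000
  stats_of <- function(tips) {
    p <- tabulate(factor(tips)) / length(tips)
    c(k = length(p), he = length(tips) / (length(tips) - 1) * (1 - sum(p^2)))
  }
  wf <- replicate(n_rep, stats_of(mutate_genealogy(wf_genealogy(10, 200), mut)))
  dm <- constant_model(100, 100, 10)
  co <- replicate(n_rep, stats_of(mutate_genealogy(
    simulate_genealogy(10, dm), mut)))
  for (s in c("k", "he")) {
    se <- sqrt(var(wf[s, ]) / n_rep + var(co[s, ]) / n_rep)
    expect_lt(abs(mean(wf[s, ]) - mean(co[s, ])), 3.5 * se)
  }
})

test_that("diploid pairing of gene copies is statistically irrelevant", {
  set.seed(107)
  d <- simulate_dataset(400, 20, constant_model(5000, 5000, 30),
                        mutation_model(1e-4))
  # summaries that ignore pairing are bitwise invariant to re-pairing
  gene_copy <- matrix(NA_integer_, 800, 20)
  gene_copy[seq(1, 799, 2), ] <- d$alleles[, , 1]
  gene_copy[seq(2, 800, 2), ] <- d$alleles[, , 2]
  reord <- gene_copy[sample(800), , drop = FALSE]
  d2 <- genotype_data(reord, "p")
  expect_equal(abc_summary_vector(d2), abc_summary_vector(d))
  # under random mating Ho tracks He whichever pairing is used
  pld <- per_locus_diversity(d)
  pld2 <- per_locus_diversity(d2)
  expect_lt(abs(mean(pld$Ho - pld$He)), 0.02)
  expect_lt(abs(mean(pld2$Ho - pld2$He)), 0.02)
})
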