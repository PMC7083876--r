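test_that("configs validate their admixture specifications", {
  expect_error(synthetic_config(list(list(name = "a"))), "n_individuals")
  expect_error(synthetic_config(list(
    list(name = "a", n_individuals = 5, ne_bot = 100, duration = 5),
    list(name = "m", n_individuals = 5, admix_from = c("a", "b"),
         proportions = c(0.7, 0.6)))), "sum to 1")
})

# reduced-size replica of the five-population default for test speed
small_cfg <- fur_seal_config(n_individuals = c(40, 60, 40, 35, 35))

test_that("the fur-seal-like preset matches its target diversity window", {
  d <- generate_multipop_dataset(small_cfg, seed = 71)
  expect_equal(nlevels(d$pop), 5)
  expect_equal(n_loci(d), 39)
  tab <- diversity_summary(d, rarefaction_g = 20)
  expect_true(all(tab$Ho > 0.6 & tab$Ho < 0.8))
  # allele counts per locus in the expected 2-26 window (loosely checked)
  k <- per_locus_diversity(d)$k
  expect_true(mean(k >= 2 & k <= 26) > 0.9)
})

test_that("admixed population sits between its sources", {
  set.seed(72)
  fst_gap <- replicate(5, {
    d <- generate_multipop_dataset(small_cfg)
    f <- pairwise_fst(d)
    mixed_to_src <- mean(c(f["MarionCrozet", "SouthGeorgia"],
                           f["MarionCrozet", "Bouvetoya"]))
    c(gap = f["SouthGeorgia", "Bouvetoya"] - mixed_to_src)
  })
  expect_gt(mean(fst_gap > 0), 0.7)
})

test_that("populations from one panmictic pool are undifferentiated", {
  cfg <- synthetic_config(list(
    list(name = "a", n_individuals = 40, ne_bot = 10000, duration = 1),
    list(name = "b", n_individuals = 40, ne_bot = 10000, duration = 1)),
    n_loci = 15)
  d <- generate_multipop_dataset(cfg, seed = 73)
  expect_lt(abs(pairwise_fst(d)["a", "b"]), 0.02)
})

test_that("generation is deterministic under a fixed seed", {
  d1 <- generate_multipop_dataset(small_cfg, seed = 74)
  d2 <- generate_multipop_dataset(small_cfg, seed = 74)
  expect_identical(d1$alleles, d2$alleles)
})

test_that("the fixture suite is regenerable and internally consistent", {
  dir1 <- tempfile("fix1")
  dir2 <- tempfile("fix2")
  m1 <- fixture_suite(dir1, seed = 5, n_ind = 25)
  m2 <- fixture_suite(dir2, seed = 5, n_ind = 25)
  for (f in c("tiny.gen", "midsize39.gen", "bottleneck.gen", "constant.gen",
              "manifest.json")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  # manifest values match the statistics recomputed from the files
  tiny <- read_genepop(file.path(dir1, "tiny.gen"))
  pld <- per_locus_diversity(tiny)
  expect_equal(pld$Ho[1], m1$tiny$hand_checked$L1$Ho)
  expect_equal(pld$He[1], m1$tiny$hand_checked$L1$He)
  expect_equal(pld$k[2], m1$tiny$hand_checked$L2$k)
  expect_equal(pld$Ho[3], m1$tiny$hand_checked$L3$Ho)
  mid <- read_genepop(file.path(dir1, "midsize39.gen"))
  expect_equal(unname(attr(per_locus_diversity(mid), "means")["Ho"]),
               m1$midsize39$Ho, tolerance = 1e-5)
  # the bottlenecked member of the pair has the lower M-ratio
  expect_lt(m1$bottleneck$M_ratio, m1$constant$M_ratio)
})
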