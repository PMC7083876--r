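# A small real reference table shared by several blocks in this file.
ref_tab <- build_reference_table(1500, n_ind = 40, n_loci = 12, seed = 401)

test_that("prior draws respect supports, moments and the time ordering", {
  pr <- abc_priors()
  draws <- sample_priors(pr, "bottleneck", 1e5, seed = 41)
  expect_true(all(draws$ne_bot >= 1 & draws$ne_bot <= 600))
  se <- sqrt(599^2 / 12 / 1e5)
  expect_lt(abs(mean(draws$ne_bot) - 300.5), 3 * se)
  expect_lt(abs(mean(log(draws$ne_cur)) - 10.5), 3 / sqrt(1e5))
  expect_lt(abs(sd(log(draws$ne_cur)) - 1), 0.02)
  expect_true(all(draws$t_bot_start > draws$t_bot_end))
  expect_true(all(draws$mu >= 1e-5 & draws$mu <= 1e-4))
  expect_true(all(draws$gsm_par >= 0 & draws$gsm_par <= 0.3))
  nb <- sample_priors(pr, "non_bottleneck", 100, seed = 42)
  expect_true(all(nb$t_hist >= 10 & nb$t_hist <= 40))
  expect_false("ne_bot" %in% names(nb))
  # the verbal preset matches its own verbal description
  pv <- abc_priors(preset = "verbal")
  q <- stats::qlnorm(c(0.05, 0.95), pv$ne_log_mean, pv$ne_log_sd)
  expect_lt(abs(q[1] - 3000) / 3000, 0.15)
  expect_lt(abs(q[2] - 15000) / 15000, 0.15)
})

test_that("reference tables have the right shape, signal and determinism", {
  expect_equal(nrow(ref_tab), 3000)
  expect_true(all(c("mean_k", "prop_low_freq", "mean_M", "model")
                  %in% names(ref_tab)))
  expect_true(all(is.finite(ref_tab$mean_k)))
  # bottleneck simulations carry a depressed M-ratio
  mw <- stats::wilcox.test(mean_M ~ model, data = ref_tab,
                           alternative = "less")
  expect_lt(mw$p.value, 1e-3)
  small1 <- build_reference_table(30, n_ind = 10, n_loci = 4, seed = 7)
  small2 <- build_reference_table(30, n_ind = 10, n_loci = 4, seed = 7)
  expect_identical(small1, small2)
})

test_that("rejection keeps the closest rows and the trivial cases", {
  target <- ref_tab[10, ]
  post <- abc_reject(target, ref_tab, tolerance = 1)
  expect_equal(nrow(post$accepted), nrow(ref_tab))   # tolerance 1 = prior
  one <- abc_reject(target, ref_tab, tolerance = 1 / nrow(ref_tab))
  expect_equal(one$distances, 0)
  expect_equal(one$accepted$mean_k, target$mean_k)
  expect_error(abc_reject(target, ref_tab, 0), "tolerance")
  expect_error(abc_reject(target, ref_tab, 2), "tolerance")
  # distances are sorted and count follows the tolerance
  p5 <- abc_reject(target, ref_tab, 0.05)
  expect_equal(nrow(p5$accepted), round(0.05 * nrow(ref_tab)))
  expect_false(is.unsorted(p5$distances))
})

test_that("row order of the reference table is irrelevant", {
  target <- c(mean_k = 8, prop_low_freq = 0.3, mean_M = 0.8)
  set.seed(43)
  perm <- ref_tab[sample(nrow(ref_tab)), ]
  attr(perm, "n_ind") <- attr(ref_tab, "n_ind")
  attr(perm, "n_loci") <- attr(ref_tab, "n_loci")
  a <- abc_reject(target, ref_tab, 0.02)
  b <- abc_reject(target, perm, 0.02)
  expect_equal(sort(a$accepted$mean_k), sort(b$accepted$mean_k))
  expect_equal(model_posterior(target, ref_tab, 0.02),
               model_posterior(target, perm, 0.02))
})

test_that("model posteriors are frequencies of accepted rows", {
  target <- c(mean_k = 8, prop_low_freq = 0.3, mean_M = 0.8)
  mp <- model_posterior(target, ref_tab, 0.05)
  expect_equal(sum(mp), 1)
  # identical generating processes => posterior ~ (0.5, 0.5)
  gen <- function(n) data.frame(mean_k = rnorm(n, 8), prop_low_freq = runif(n),
                                mean_M = runif(n))
  fake <- fake_reference_table(4000, gen, gen, seed = 44)
  mp2 <- model_posterior(c(mean_k = 8, prop_low_freq = 0.5, mean_M = 0.5),
                         fake, 0.1)
  expect_lt(abs(mp2[["bottleneck"]] - 0.5), 0.1)
})

test_that("model-selection cross-validation hits the two trivial regimes", {
  # disjoint summary distributions: perfect classification
  gb <- function(n) data.frame(mean_k = rnorm(n, 0, 0.1),
                               prop_low_freq = rnorm(n, 0, 0.1),
                               mean_M = rnorm(n, 0, 0.1))
  gc_ <- function(n) data.frame(mean_k = rnorm(n, 10, 0.1),
                                prop_low_freq = rnorm(n, 10, 0.1),
                                mean_M = rnorm(n, 10, 0.1))
  cv <- cv_model_selection(fake_reference_table(1500, gb, gc_, seed = 45),
                           n_pseudo = 60, tolerance = 0.02, seed = 46)
  expect_equal(unname(cv$correct_rate), c(1, 1))
  # identical distributions: coin toss
  cv2 <- cv_model_selection(fake_reference_table(1500, gb, gb, seed = 47),
                            n_pseudo = 100, tolerance = 0.05, seed = 48)
  expect_true(all(abs(cv2$correct_rate - 0.5) < 0.2))
  expect_equal(dim(cv2$confusion), c(2, 2))
})

test_that("prediction error is 0 for a perfect and ~1 for a blind estimator", {
  # summaries reveal the parameter exactly -> nearest rows share theta
  n <- 4000
  gen_exact <- function(n) {
    th <- runif(n, 0, 100)
    data.frame(ne_bot = th, mean_k = th, prop_low_freq = th, mean_M = th)
  }
  set.seed(49)
  tab <- data.frame(model = "bottleneck", gen_exact(n))
  class(tab) <- c("reference_table", "data.frame")
  cv <- cv_parameter_estimation(tab, params = "ne_bot", n_pseudo = 100,
                                tolerance = 0.002, seed = 50)
  expect_lt(cv$e_pred[["ne_bot"]], 0.01)
  # summaries carry no information -> error ~ 1
  gen_blind <- function(n) {
    data.frame(ne_bot = runif(n, 0, 100), mean_k = rnorm(n),
               prop_low_freq = rnorm(n), mean_M = rnorm(n))
  }
  tab2 <- data.frame(model = "bottleneck", gen_blind(n))
  class(tab2) <- c("reference_table", "data.frame")
  cv2 <- cv_parameter_estimation(tab2, params = "ne_bot", n_pseudo = 150,
                                 tolerance = 0.05, seed = 51)
  expect_lt(abs(cv2$e_pred[["ne_bot"]] - 1), 0.25)
  expect_error(cv_parameter_estimation(ref_tab, tolerance = 0.01),
               "single-model")
})

test_that("posterior predictive checks are self-consistent", {
  bot_tab <- ref_tab[ref_tab$model == "bottleneck", ]
  attr(bot_tab, "n_ind") <- attr(ref_tab, "n_ind")
  attr(bot_tab, "n_loci") <- attr(ref_tab, "n_loci")
  target <- bot_tab[25, ]
  post <- abc_reject(target, bot_tab, 0.1)
  one <- posterior_predictive_check(post, n_draws = 1, seed = 52)
  expect_equal(dim(one$sims), c(1, 3))
  ppc <- posterior_predictive_check(post, n_draws = 300, seed = 53)
  expect_true(all(ppc$tail_prob > 0.01 & ppc$tail_prob < 0.99))
  expect_true(all(ppc$p_two_sided > 0 & ppc$p_two_sided <= 1))
})

test_that("goodness of fit separates plausible from impossible targets", {
  target <- ref_tab[100, ]
  g <- goodness_of_fit(target, ref_tab, 0.05, n_null = 60, seed = 54)
  expect_gt(g$p_value, 1 / 61)
  expect_lte(g$p_value, 1)
  far <- c(mean_k = 1e4, prop_low_freq = 50, mean_M = -40)
  g2 <- goodness_of_fit(far, ref_tab, 0.05, n_null = 60, seed = 55)
  expect_equal(g2$p_value, 1 / 61)
})

test_that("reference tables survive the CSV round trip with their metadata", {
  f <- tempfile(fileext = ".csv")
  write_reference_table(ref_tab, f)
  r <- read_reference_table(f)
  expect_equal(attr(r, "n_ind"), attr(ref_tab, "n_ind"))
  expect_equal(attr(r, "n_loci"), attr(ref_tab, "n_loci"))
  expect_equal(r$mean_k, ref_tab$mean_k, tolerance = 1e-12)
  expect_equal(r$model, ref_tab$model)
})
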