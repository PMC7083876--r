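#' Default configuration for the full analysis pipeline
#'
#' @param input Either the name of a synthetic preset (currently
#'   `"fur_seal"`) or a path to a GENEPOP (`.gen`) or tidy CSV genotype file.
#' @param seed Global integer seed; every stage derives its own seed
#'   deterministically from this and the stage name.
#' @param n_abc_sims Reference-table simulations per model.
#' @param abc_tolerance Rejection tolerance.
#' @param abc_target_n Individuals per population used for the empirical
#'   target summaries; larger populations are subsampled to this size so
#'   observed and simulated samples match.
#' @param het_iter Equilibrium replicates per locus for the
#'   heterozygosity-excess test.
#' @param het_model Mutation model assumed by the heterozygosity-excess test:
#'   `"tpm80"` (the conventional two-phase default), `"smm"`, or `"gsm"`
#'   (generalized stepwise with 20\% multistep, matching the synthetic
#'   presets; use this for calibration studies, as a mismatch between the
#'   assumed and generating step law biases the test).
#' @param loss_sims Simulations per model per loss scenario.
#' @param loss_grid Logical: also compute the strength-by-duration loss grid
#'   (time-consuming at full resolution).
#' @param rarefaction_g Gene copies for rarefied allelic richness.
#' @param preset_n Optional vector of per-population sample sizes overriding
#'   the synthetic preset defaults (useful for quick runs).
#' @return A named list (class `run_config`).
#' @export
run_config <- function(input = "fur_seal", seed = 1, n_abc_sims = 5000,
                       abc_tolerance = 0.01, abc_target_n = 181,
                       het_iter = 1000, het_model = "tpm80",
                       loss_sims = 2000, loss_grid = FALSE,
                       rarefaction_g = 20, preset_n = NULL) {
  structure(list(input = input, seed = seed, n_abc_sims = n_abc_sims,
                 abc_tolerance = abc_tolerance, abc_target_n = abc_target_n,
                 het_iter = het_iter, het_model = het_model,
                 loss_sims = loss_sims,
                 loss_grid = loss_grid, rarefaction_g = rarefaction_g,
                 preset_n = preset_n),
            class = "run_config")
}

#' @rdname run_config
#' @param path Path to a YAML file with any subset of the `run_config`
#'   fields.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  cfg <- run_config()
  cfg[names(vals)] <- vals
  cfg
}

# Deterministic per-stage seed below 2^31, derived from the global seed.
stage_seed <- function(seed, stage) {
  h <- rlang::hash(list(seed = seed, stage = stage))
  strtoi(substr(h, 1, 7), base = 16L)
}

#' Run the full demographic-reconstruction analysis
#'
#' Orchestrates every stage on one dataset: per-population diversity
#' statistics, pairwise Fst, the heterozygosity-excess bottleneck test, ABC
#' model selection and Ne_bot posterior estimation, and the expected
#' allele-loss scenarios. All outputs are written under `out_dir` (CSV per
#' stage plus a machine-readable `summary.json` stamped with the seed and a
#' hash of the configuration); the summary is also returned.
#'
#' @param cfg A [run_config] (or a YAML path accepted by
#'   [read_run_config]).
#' @param out_dir Output directory, created if needed.
#' @param quiet Suppress progress messages.
#' @return The summary list, invisibly.
#' @export
run_full_analysis <- function(cfg = run_config(), out_dir, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  cfg_hash <- rlang::hash(unclass(cfg))
  t0 <- proc.time()[["elapsed"]]

  stage <- "load"
  summary <- list(seed = cfg$seed, config_hash = cfg_hash,
                  version = as.character(utils::packageVersion("msatABC")))
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  preset <- function() {
    if (is.null(cfg$preset_n)) fur_seal_config() else
      fur_seal_config(n_individuals = cfg$preset_n)
  }
  d <- run_stage("load", function() {
    if (identical(cfg$input, "fur_seal")) {
      generate_multipop_dataset(preset(),
                                seed = stage_seed(cfg$seed, "synthetic"))
    } else if (identical(cfg$input, "constant")) {
      # negative-control preset: same layout, no bottlenecks
      pops <- preset()$populations
      for (i in seq_along(pops)) {
        if (is.null(pops[[i]]$admix_from)) pops[[i]]$ne_bot <- 10000
      }
      generate_multipop_dataset(synthetic_config(pops),
                                seed = stage_seed(cfg$seed, "synthetic"))
    } else if (grepl("\\.csv$", cfg$input)) {
      read_genotype_csv(cfg$input)
    } else {
      read_genepop(cfg$input)
    }
  })
  say("loaded %d individuals x %d loci", n_individuals(d), n_loci(d))

  say("stage: diversity statistics")
  div <- run_stage("diversity", function() {
    diversity_summary(d, rarefaction_g = cfg$rarefaction_g)
  })
  write_report_csv(div, file.path(out_dir, "diversity.csv"), seed = cfg$seed)
  fst <- NULL
  if (nlevels(d$pop) >= 2) {
    fst <- run_stage("fst", function() {
      pairwise_fst(d, n_boot = 200, seed = stage_seed(cfg$seed, "fst"))
    })
    write_report_csv(fst, file.path(out_dir, "fst.csv"), seed = cfg$seed)
  }
  summary$diversity <- div

  say("stage: heterozygosity-excess tests")
  cache <- new_het_null_cache()
  het_mut <- switch(cfg$het_model,
                    tpm80 = tpm80(),
                    smm = mutation_model(1e-4, 0),
                    gsm = mutation_model(9e-5, 0.2),
                    stop("unknown het_model: ", cfg$het_model))
  set.seed(stage_seed(cfg$seed, "hetexcess"))
  het <- run_stage("het_excess", function() {
    lapply(stats::setNames(levels(d$pop), levels(d$pop)), function(p) {
      r <- het_excess_test(subset_pops(d, p), mut = het_mut,
                           n_iter = cfg$het_iter, null_cache = cache)
      write_report_csv(r$per_locus,
                       file.path(out_dir, paste0("hetexcess_", p, ".csv")),
                       seed = cfg$seed)
      r[c("prop_het_exc", "n_loci_excess", "n_loci_used", "p_sign",
          "p_std_diff", "p_wilcoxon")]
    })
  })
  summary$het_excess <- het

  say("stage: ABC (reference table of %d x 2 simulations)", cfg$n_abc_sims)
  abc <- run_stage("abc", function() {
    # simulated sample size must match the size of the observed targets
    tab <- build_reference_table(cfg$n_abc_sims, n_ind = cfg$abc_target_n,
                                 seed = stage_seed(cfg$seed, "abc_table"))
    set.seed(stage_seed(cfg$seed, "abc_targets"))
    per_pop <- lapply(stats::setNames(levels(d$pop), levels(d$pop)),
                      function(p) {
      sub <- subset_pops(d, p)
      if (n_individuals(sub) > cfg$abc_target_n) {
        keep <- sample(n_individuals(sub), cfg$abc_target_n)
        sub <- genotype_data(sub$alleles[keep, , , drop = FALSE],
                             sub$pop[keep], loci = sub$loci)
      }
      target <- abc_summary_vector(sub)
      mp <- model_posterior(target, tab, cfg$abc_tolerance)
      post <- abc_reject(target,
                         tab[tab$model == "bottleneck", , drop = FALSE],
                         cfg$abc_tolerance)
      gof <- goodness_of_fit(target, tab[tab$model == "bottleneck", ,
                                         drop = FALSE],
                             cfg$abc_tolerance, n_null = 50)
      list(target = as.list(target),
           p_bottleneck = unname(mp["bottleneck"]),
           ne_bot_median = stats::median(post$accepted$ne_bot),
           ne_bot_q = stats::quantile(post$accepted$ne_bot, c(0.05, 0.95)),
           gof_p = gof$p_value)
    })
    list(per_population = per_pop)
  })
  summary$abc <- abc

  say("stage: expected allele loss scenarios")
  loss <- run_stage("loss", function() {
    sc <- loss_scenarios(n_sims = cfg$loss_sims,
                         seed = stage_seed(cfg$seed, "loss"))
    out <- list(scenarios = sc$summary)
    write_report_csv(sc$summary, file.path(out_dir, "loss_scenarios.csv"),
                     seed = cfg$seed)
    if (isTRUE(cfg$loss_grid)) {
      gr <- loss_grid(n_sims_per_cell = 200,
                      seed = stage_seed(cfg$seed, "loss_grid"))
      write_report_csv(as.data.frame(gr), file.path(out_dir, "loss_grid.csv"),
                       seed = cfg$seed)
      out$grid <- as.data.frame(gr)
    }
    out
  })
  summary$loss <- loss
  summary$elapsed_s <- round(proc.time()[["elapsed"]] - t0, 1)

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  say("done in %.1f s; outputs in %s", summary$elapsed_s, out_dir)
  invisible(summary)
}
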