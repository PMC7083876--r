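#' Configuration for the synthetic multi-population generator
#'
#' Describes a set of populations sharing one ancestral gene pool. Each
#' population either drifts independently through its own (bottleneck or
#' constant) recent demography, or is an admixture of other populations.
#' Differentiation between populations arises from independent drift out of
#' the shared ancestral pool; this emulates the structure of a set of relict
#' populations re-founded after exploitation and is not a joint
#' multi-population coalescent.
#'
#' @param populations List of population specs. Each spec is a list with
#'   `name`, `n_individuals` and either drift parameters `ne_bot`,
#'   `duration`, `t_end` (generations of post-bottleneck drift at large
#'   size are ignored, as negligible) or an admixture spec `admix_from`
#'   (character vector of source population names) with `proportions`
#'   (summing to 1).
#' @param n_loci Number of loci.
#' @param mut A [mutation_model] used for the ancestral equilibrium pool.
#' @param ne_hist Diploid effective size of the shared ancestral population.
#' @param pool_copies Gene copies drawn from the ancestral coalescent per
#'   locus (the ancestral allele-frequency pool). Must stay much larger than
#'   any population sample, or resampling clips the rare-allele tail and
#'   mimics a bottleneck signature.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(populations, n_loci = 39,
                             mut = mutation_model(9e-5, p_multistep = 0.2),
                             ne_hist = 10000, pool_copies = 20000) {
  for (p in populations) {
    if (is.null(p$name) || is.null(p$n_individuals)) {
      stop("every population needs a name and n_individuals")
    }
    if (!is.null(p$admix_from)) {
      if (length(p$admix_from) != length(p$proportions)) {
        stop("admix_from and proportions must have equal length")
      }
      if (abs(sum(p$proportions) - 1) > 1e-8) {
        stop("mixing proportions must sum to 1")
      }
    }
  }
  structure(list(populations = populations, n_loci = n_loci, mut = mut,
                 ne_hist = ne_hist, pool_copies = pool_copies),
            class = "synthetic_config")
}

#' Fur-seal-like preset configuration
#'
#' Five populations with the sample sizes of a range-wide pinniped survey
#' (197, 1042, 396, 184 and 181 diploids), 39 loci, four populations having
#' passed a bottleneck of effective size 200 for ten generations ending ten
#' generations ago, and one admixed population drawing equally from two
#' neighbours. The ancestral size (10,000) and mutation model (rate 9e-5,
#' 20\% multistep) are calibrated to give heterozygosities near 0.7 and
#' M-ratios near 0.8, typical of the system this emulates.
#'
#' @param n_individuals Sample sizes of the five populations.
#' @return A [synthetic_config].
#' @export
fur_seal_config <- function(n_individuals = c(197, 1042, 396, 184, 181)) {
  bn <- function(name, n) list(name = name, n_individuals = n,
                               ne_bot = 200, duration = 10, t_end = 10)
  synthetic_config(list(
    bn("SouthShetlands", n_individuals[1]),
    bn("SouthGeorgia", n_individuals[2]),
    bn("Bouvetoya", n_individuals[3]),
    list(name = "MarionCrozet", n_individuals = n_individuals[4],
         admix_from = c("SouthGeorgia", "Bouvetoya"),
         proportions = c(0.5, 0.5)),
    bn("KerguelenHeardMacquarie", n_individuals[5])
  ))
}

# Drift an allele-count vector through g generations of Wright-Fisher
# multinomial resampling at 2N gene copies; returns relative frequencies.
drift_freqs <- function(freqs, two_n, generations) {
  for (g in seq_len(generations)) {
    freqs <- stats::rmultinom(1, two_n, freqs)[, 1] / two_n
  }
  freqs
}

#' Generate a multi-population synthetic genotype dataset
#'
#' Per locus, an ancestral allele pool is drawn from the equilibrium
#' coalescent at `ne_hist`; each drifting population then resamples those
#' frequencies through its bottleneck generations (Wright-Fisher multinomial
#' resampling at `2 * ne_bot` copies), and individuals' gene copies are drawn
#' from the resulting population frequencies. Admixed populations draw each
#' gene copy from a source population chosen by the mixing proportions.
#'
#' @param cfg A [synthetic_config].
#' @param seed Optional integer seed.
#' @return A [genotype_data] object.
#' @examples
#' \donttest{
#' cfg <- fur_seal_config(n_individuals = rep(30, 5))
#' d <- generate_multipop_dataset(cfg, seed = 1)
#' }
#' @export
generate_multipop_dataset <- function(cfg, seed = NULL) {
  if (!inherits(cfg, "synthetic_config")) stop("cfg must be a synthetic_config")
  if (!is.null(seed)) set.seed(seed)
  pops <- cfg$populations
  names(pops) <- vapply(pops, `[[`, character(1), "name")
  drifting <- names(pops)[vapply(pops, function(p) is.null(p$admix_from),
                                 logical(1))]
  admixed <- setdiff(names(pops), drifting)
  n_tot <- sum(vapply(pops, `[[`, numeric(1), "n_individuals"))
  arr <- array(NA_integer_, dim = c(n_tot, cfg$n_loci, 2))
  pop_labels <- rep(names(pops),
                    times = vapply(pops, `[[`, numeric(1), "n_individuals"))
  offsets <- c(0, cumsum(vapply(pops, `[[`, numeric(1), "n_individuals")))
  names(offsets) <- c(names(pops), "end")
  anc <- constant_model(cfg$ne_hist, cfg$ne_hist, 1000)
  pool <- .cpp_sim_dataset(cfg$pool_copies, cfg$n_loci, anc$start_time,
                           anc$ne, cfg$mut$mu, cfg$mut$p_multistep,
                           cfg$mut$q_multi, 50L)
  for (l in seq_len(cfg$n_loci)) {
    alleles <- sort(unique(pool[, l]))
    p0 <- tabulate(factor(pool[, l], levels = alleles)) / cfg$pool_copies
    pop_freqs <- list()
    for (nm in drifting) {
      p <- pops[[nm]]
      pop_freqs[[nm]] <- drift_freqs(p0, 2 * p$ne_bot, p$duration)
    }
    for (nm in admixed) {
      p <- pops[[nm]]
      f <- Reduce(`+`, Map(function(src, w) w * pop_freqs[[src]],
                           p$admix_from, p$proportions))
      pop_freqs[[nm]] <- f
    }
    for (nm in names(pops)) {
      n <- pops[[nm]]$n_individuals
      idx <- offsets[nm] + seq_len(n)
      draw_from <- function(freqs, m) {
        alleles[sample.int(length(alleles), m, replace = TRUE, prob = freqs)]
      }
      if (nm %in% admixed) {
        p <- pops[[nm]]
        draw_copy <- function(m) {
          src <- sample.int(length(p$admix_from), m, replace = TRUE,
                            prob = p$proportions)
          out <- integer(m)
          for (s in unique(src)) {
            sel <- src == s
            out[sel] <- draw_from(pop_freqs[[p$admix_from[s]]], sum(sel))
          }
          out
        }
        arr[idx, l, 1] <- draw_copy(n)
        arr[idx, l, 2] <- draw_copy(n)
      } else {
        arr[idx, l, 1] <- draw_from(pop_freqs[[nm]], n)
        arr[idx, l, 2] <- draw_from(pop_freqs[[nm]], n)
      }
    }
  }
  genotype_data(arr, pop_labels)
}

#' Write a deterministic suite of small genotype fixtures
#'
#' Creates, under `dir`: a tiny hand-checkable 3-locus dataset (`tiny.csv`,
#' `tiny.gen`), a mid-size 39-locus single-population dataset
#' (`midsize39.gen`), a bottlenecked/constant dataset pair
#' (`bottleneck.gen`, `constant.gen`), and a `manifest.json` recording the
#' seed and the summary statistics of each file.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; the same seed regenerates identical files.
#' @param n_ind Individuals per simulated fixture (kept small so fixtures
#'   stay a few kilobytes).
#' @return Invisibly, the manifest as a list.
#' @export
fixture_suite <- function(dir, seed = 1, n_ind = 60) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  tiny <- tiny_fixture()
  write_genotype_csv(tiny, file.path(dir, "tiny.csv"), seed = seed)
  write_genepop(tiny, file.path(dir, "tiny.gen"))
  mid <- simulate_dataset(n_ind, 39, bottleneck_model(10000, 200, 10000, 10, 20),
                          mutation_model(9e-5, 0.2), pop = "mid")
  write_genepop(mid, file.path(dir, "midsize39.gen"))
  bot <- simulate_dataset(n_ind, 39, bottleneck_model(10000, 200, 10000, 10, 20),
                          mutation_model(9e-5, 0.2), pop = "bottlenecked")
  con <- simulate_dataset(n_ind, 39, constant_model(10000, 10000, 20),
                          mutation_model(9e-5, 0.2), pop = "constant")
  write_genepop(bot, file.path(dir, "bottleneck.gen"))
  write_genepop(con, file.path(dir, "constant.gen"))
  summarise <- function(d) {
    m <- attr(per_locus_diversity(d), "means")
    as.list(round(m, 6))
  }
  manifest <- list(
    seed = seed,
    tiny = c(summarise(tiny), list(hand_checked = list(
      L1 = list(Ho = 0.5, He = 0.5, k = 2),
      L2 = list(Ho = 0.0, He = 0.0, k = 1),
      L3 = list(Ho = 1.0, k = 4)))),
    midsize39 = summarise(mid),
    bottleneck = summarise(bot),
    constant = summarise(con)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Two individuals, three loci, two populations; statistics checkable by hand:
# L1 in pop-pooled form has genotypes (10,11) and (10,10): Ho = 0.5,
# unbiased He = 0.5; L2 monomorphic; L3 all four copies distinct.
tiny_fixture <- function() {
  arr <- array(NA_integer_, dim = c(2, 3, 2))
  arr[1, , 1] <- c(10L, 7L, 20L)
  arr[1, , 2] <- c(11L, 7L, 21L)
  arr[2, , 1] <- c(10L, 7L, 22L)
  arr[2, , 2] <- c(10L, 7L, 23L)
  genotype_data(arr, pop = c("popA", "popB"), loci = c("L1", "L2", "L3"))
}
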