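#' Simulate a coalescent genealogy under a piecewise-constant demography
#'
#' Runs the single-population Kingman coalescent backwards in time: with `k`
#' ancestral lineages and diploid size `Ne(t)`, the next coalescence occurs
#' at rate `choose(k, 2) / (2 * Ne(t))`. Waiting times are carried across
#' epoch boundaries by time rescaling, so epoch changes are handled exactly.
#'
#' Nodes are indexed `1..n` for tips (time 0) and `n+1 .. 2n-1` for internal
#' nodes in coalescence order; the root is node `2n-1`.
#'
#' @param n_lineages Number of sampled gene copies (>= 1).
#' @param demography A [demographic_model].
#' @param seed Optional integer seed (calls `set.seed()`).
#' @return An object of class `genealogy`: list with `parent` (1-based parent
#'   pointers, `NA` at the root), `time` (node times, generations before
#'   present) and `n_tips`.
#' @examples
#' g <- simulate_genealogy(10, constant_model(1000, 1000, 50), seed = 1)
#' tmrca(g)
#' @export
simulate_genealogy <- function(n_lineages, demography, seed = NULL) {
  if (!inherits(demography, "demographic_model")) {
    stop("demography must be a demographic_model")
  }
  n_lineages <- as.integer(n_lineages)
  if (is.na(n_lineages) || n_lineages < 1) stop("n_lineages must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  g <- .cpp_sim_genealogy(n_lineages, demography$start_time, demography$ne)
  structure(g, class = "genealogy")
}

#' @rdname simulate_genealogy
#' @param g A `genealogy` object.
#' @export
tmrca <- function(g) max(g$time)

#' @rdname simulate_genealogy
#' @export
total_branch_length <- function(g) {
  if (g$n_tips == 1) return(0)
  br <- g$time[g$parent[!is.na(g$parent)]] - g$time[!is.na(g$parent)]
  sum(br)
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf("Coalescent genealogy: %d tips, TMRCA = %.1f generations\n",
              x$n_tips, tmrca(x)))
  invisible(x)
}

#' Convert a genealogy to an ape "phylo" tree
#'
#' @param g A `genealogy` object with at least 2 tips.
#' @return An object of class `phylo` (requires the ape package).
#' @export
genealogy_to_phylo <- function(g) {
  if (!requireNamespace("ape", quietly = TRUE)) stop("ape is not installed")
  n <- g$n_tips
  if (n < 2) stop("need at least 2 tips")
  # ape numbering: tips 1..n, root n+1, then internal nodes. Our internal
  # node n+k (k-th merge) has ape id 2n - k.
  remap <- c(seq_len(n), rev(n + seq_len(n - 1)))
  child <- which(!is.na(g$parent))
  edge <- cbind(remap[g$parent[child]], remap[child])
  lens <- g$time[g$parent[child]] - g$time[child]
  structure(list(edge = edge, edge.length = lens,
                 tip.label = paste0("t", seq_len(n)), Nnode = n - 1L),
            class = "phylo", order = "unknown")
}

#' Drop stepwise mutations onto a genealogy
#'
#' Mutation counts on each branch are Poisson with mean `mu` times branch
#' length; each mutation perturbs the allele size by a signed step drawn from
#' the model's step law (see [mutation_model]). Allele states are propagated
#' from the root (at `root_allele`) to the tips.
#'
#' @param g A `genealogy` from [simulate_genealogy].
#' @param mut A [mutation_model].
#' @param root_allele Allele size (repeat units) at the root; the default 50
#'   is an arbitrary origin, as every statistic in the package is invariant
#'   to allele-size translation.
#' @param seed Optional integer seed.
#' @return Integer vector of tip allele sizes, in tip order.
#' @export
mutate_genealogy <- function(g, mut, root_allele = 50L, seed = NULL) {
  if (!inherits(mut, "mutation_model")) stop("mut must be a mutation_model")
  if (!is.null(seed)) set.seed(seed)
  .cpp_mutate_genealogy(g$parent, g$time, g$n_tips, mut$mu, mut$p_multistep,
                        mut$q_multi, as.integer(root_allele))
}

#' Simulate a complete single-population microsatellite dataset
#'
#' One independent genealogy is drawn per locus over `2 * n_individuals` gene
#' copies and mutated under the stepwise model; gene copies are then paired
#' sequentially into diploids (copies `2i-1, 2i` form individual `i`), which
#' under random mating is equivalent to any other pairing.
#'
#' @param n_individuals Number of diploid individuals (>= 1).
#' @param n_loci Number of unlinked loci (>= 1).
#' @param demography A [demographic_model].
#' @param mut A [mutation_model].
#' @param root_allele Ancestral allele size in repeat units.
#' @param pop Population label for all individuals.
#' @param seed Optional integer seed.
#' @return A [genotype_data] object with no missing data.
#' @examples
#' d <- simulate_dataset(20, 5, constant_model(1000, 1000, 50),
#'                       mutation_model(5e-4), seed = 1)
#' @export
simulate_dataset <- function(n_individuals, n_loci, demography, mut,
                             root_allele = 50L, pop = "pop1", seed = NULL) {
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  if (n_loci < 1) stop("n_loci must be >= 1")
  if (!inherits(demography, "demographic_model")) {
    stop("demography must be a demographic_model")
  }
  if (!inherits(mut, "mutation_model")) stop("mut must be a mutation_model")
  if (!is.null(seed)) set.seed(seed)
  m <- .cpp_sim_dataset(2L * n_individuals, as.integer(n_loci),
                        demography$start_time, demography$ne,
                        mut$mu, mut$p_multistep, mut$q_multi,
                        as.integer(root_allele))
  genotype_data(m, pop = pop)
}
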