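#' Diploid microsatellite genotype container
#'
#' The universal data structure of the package: an
#' `n_individuals x n_loci x 2` integer array of allele sizes in repeat
#' units (`NA` = missing gene copy), plus a population label per individual.
#'
#' @param alleles Integer array `n x L x 2` of repeat counts, or an
#'   `2n x L` matrix of gene copies (rows `2i-1, 2i` = individual `i`).
#' @param pop Population labels, length `n` (coerced to factor).
#' @param loci Optional locus names (default `L1..`).
#' @param repeat_bp Optional per-locus motif length in bp, for base-pair
#'   conversion when writing 3-digit GENEPOP codes.
#' @return An object of class `genotype_data` with elements `alleles`, `pop`,
#'   `loci`, `repeat_bp`.
#' @examples
#' a <- array(c(10L, 10L, 11L, 12L), dim = c(1, 2, 2))
#' genotype_data(a, pop = "p1")
#' @export
genotype_data <- function(alleles, pop, loci = NULL, repeat_bp = NULL) {
  if (is.matrix(alleles)) {
    if (nrow(alleles) %% 2 != 0) stop("gene-copy matrix needs an even row count")
    n <- nrow(alleles) / 2
    L <- ncol(alleles)
    arr <- array(NA_integer_, dim = c(n, L, 2))
    arr[, , 1] <- alleles[seq(1, 2 * n, by = 2), , drop = FALSE]
    arr[, , 2] <- alleles[seq(2, 2 * n, by = 2), , drop = FALSE]
    alleles <- arr
  }
  if (length(dim(alleles)) != 3 || dim(alleles)[3] != 2) {
    stop("alleles must be an n x L x 2 array")
  }
  storage.mode(alleles) <- "integer"
  n <- dim(alleles)[1]
  L <- dim(alleles)[2]
  if (L < 1) stop("need at least one locus")
  if (any(alleles <= 0, na.rm = TRUE)) {
    stop("allele sizes must be positive integers")
  }
  pop <- rep_len(as.character(pop), n)
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  if (length(loci) != L) stop("loci names must match locus count")
  if (!is.null(repeat_bp) && length(repeat_bp) != L) {
    stop("repeat_bp must have one entry per locus")
  }
  dimnames(alleles) <- list(NULL, loci, NULL)
  structure(list(alleles = alleles, pop = factor(pop), loci = loci,
                 repeat_bp = repeat_bp),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("genotype_data: %d individuals x %d loci, %d population(s)\n",
              n_individuals(x), n_loci(x), nlevels(x$pop)))
  tb <- table(x$pop)
  cat("  ", paste(sprintf("%s: %d", names(tb), tb), collapse = ", "), "\n")
  miss <- mean(is.na(x$alleles))
  cat(sprintf("  missing gene copies: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @rdname genotype_data
#' @param d A `genotype_data` object.
#' @export
n_individuals <- function(d) dim(d$alleles)[1]

#' @rdname genotype_data
#' @export
n_loci <- function(d) dim(d$alleles)[2]

#' Subset a genotype dataset to one or more populations
#'
#' @param d A `genotype_data` object.
#' @param pops Character vector of population labels to keep.
#' @return A `genotype_data` object.
#' @export
subset_pops <- function(d, pops) {
  keep <- d$pop %in% pops
  if (!any(keep)) stop("no individuals in the requested population(s)")
  genotype_data(d$alleles[keep, , , drop = FALSE], droplevels(d$pop[keep]),
                loci = d$loci, repeat_bp = d$repeat_bp)
}

# Internal: 2n x L gene-copy matrix (rows 2i-1, 2i are individual i).
gene_copy_matrix <- function(d) {
  n <- n_individuals(d)
  L <- n_loci(d)
  m <- matrix(NA_integer_, 2 * n, L)
  m[seq(1, 2 * n, 2), ] <- d$alleles[, , 1]
  m[seq(2, 2 * n, 2), ] <- d$alleles[, , 2]
  colnames(m) <- d$loci
  m
}

# Internal: non-missing gene copies for one locus, optionally one population.
locus_copies <- function(d, l, pops = NULL) {
  a <- d$alleles[, l, ]
  if (!is.null(pops)) a <- a[d$pop %in% pops, , drop = FALSE]
  as.vector(a[!is.na(a)])
}
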