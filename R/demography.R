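#' Piecewise-constant demographic models
#'
#' A demographic model is an ordered set of epochs on a backwards time axis
#' (generations before present). Epoch `i` is active from `start_time[i]`
#' until the start of the next epoch; the last epoch extends to infinity.
#' Sizes are diploid effective population sizes, so `k` ancestral lineages
#' coalesce at rate `choose(k, 2) / (2 * Ne)` per generation.
#'
#' `bottleneck_model()` builds the three-epoch shape used throughout this
#' package: a present-day size `ne_cur`, a reduced size `ne_bot` between
#' `t_bot_end` and `t_bot_start` generations ago, and a historical size
#' `ne_hist` before that. `constant_model()` builds the matched two-epoch
#' shape with no bottleneck; `demographic_model()` accepts arbitrary epochs.
#'
#' @param start_time Numeric vector of epoch start times (generations before
#'   present), strictly increasing, first element 0.
#' @param ne Numeric vector of diploid effective sizes, one per epoch, all
#'   positive.
#' @param ne_cur,ne_bot,ne_hist Present-day, bottleneck and historical diploid
#'   effective sizes.
#' @param t_bot_end,t_bot_start Bottleneck end and start times in generations
#'   before present; `t_bot_start > t_bot_end > 0`.
#' @param t_hist Time (generations ago) at which the constant model switches
#'   from `ne_cur` to `ne_hist`.
#' @param shape Label for the epoch shape; set automatically by the wrappers.
#' @return An object of class `demographic_model`: a list with elements
#'   `start_time`, `ne` and `shape` (`"bottleneck"`, `"constant"` or
#'   `"custom"`).
#' @examples
#' bottleneck_model(10000, 200, 10000, t_bot_end = 10, t_bot_start = 20)
#' constant_model(5000, 5000, t_hist = 25)
#' @export
demographic_model <- function(start_time, ne, shape = "custom") {
  start_time <- as.numeric(start_time)
  ne <- as.numeric(ne)
  if (length(start_time) != length(ne) || length(ne) < 1) {
    stop("start_time and ne must be non-empty vectors of equal length")
  }
  if (start_time[1] != 0) stop("first epoch must start at time 0")
  if (length(start_time) > 1 && any(diff(start_time) <= 0)) {
    stop("epoch start times must be strictly increasing")
  }
  if (any(!is.finite(ne)) || any(ne <= 0)) stop("all Ne must be positive")
  structure(list(start_time = start_time, ne = ne, shape = shape),
            class = "demographic_model")
}

#' @rdname demographic_model
#' @export
bottleneck_model <- function(ne_cur, ne_bot, ne_hist, t_bot_end, t_bot_start) {
  if (t_bot_end <= 0) stop("t_bot_end must be positive")
  if (t_bot_start <= t_bot_end) {
    stop("t_bot_start must be greater than t_bot_end")
  }
  demographic_model(c(0, t_bot_end, t_bot_start), c(ne_cur, ne_bot, ne_hist),
                    shape = "bottleneck")
}

#' @rdname demographic_model
#' @export
constant_model <- function(ne_cur, ne_hist, t_hist) {
  if (t_hist <= 0) stop("t_hist must be positive")
  demographic_model(c(0, t_hist), c(ne_cur, ne_hist), shape = "constant")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("Demographic model (", x$shape, "), ", length(x$ne), " epochs\n",
      sep = "")
  ends <- c(x$start_time[-1], Inf)
  for (i in seq_along(x$ne)) {
    cat(sprintf("  [%g, %g) generations ago: Ne = %g\n",
                x$start_time[i], ends[i], x$ne[i]))
  }
  invisible(x)
}

#' Microsatellite mutation models
#'
#' Mutations arrive on genealogy branches as a Poisson process with rate `mu`
#' per locus per generation; each mutation shifts the allele size (in repeat
#' units) by a random signed step with symmetric direction.
#'
#' Two step-size laws are supported:
#' \describe{
#'   \item{GSM (default, `variance_target = NULL`)}{The generalized stepwise
#'     model: step magnitudes follow a geometric law
#'     `P(|S| = s) = (1 - p) p^(s-1)` for `s >= 1`, where
#'     `p = p_multistep`. The proportion of multistep mutations is exactly
#'     `p`.}
#'   \item{TPM (set `variance_target`)}{A two-phase model: single-step with
#'     probability `1 - p_multistep`, otherwise a multistep jump of size
#'     `2 + G` with `G` geometric, its parameter chosen so the variance of
#'     the multistep magnitude matches `variance_target`.}
#' }
#'
#' `tpm80()` is the classic heterozygosity-excess preset: 80\% single-step
#' mutations with multistep variance 30.
#'
#' @param mu Mutation rate per locus per generation (>= 0).
#' @param p_multistep Probability that a mutation is multistep, in `[0, 1)`.
#' @param variance_target Variance of the multistep magnitude for the
#'   two-phase law, or `NULL` for the generalized stepwise law.
#' @return An object of class `mutation_model`.
#' @examples
#' mutation_model(5e-4, p_multistep = 0.2)  # GSM with 20% multistep
#' tpm80()
#' @export
mutation_model <- function(mu, p_multistep = 0, variance_target = NULL) {
  if (!is.finite(mu) || mu < 0) stop("mu must be non-negative")
  if (p_multistep < 0 || p_multistep >= 1) {
    stop("p_multistep must be in [0, 1)")
  }
  q_multi <- -1
  if (!is.null(variance_target)) {
    if (variance_target <= 0) stop("variance_target must be positive")
    # Var(2 + G) = q / (1-q)^2 = v  =>  v q^2 - (2v + 1) q + v = 0
    v <- variance_target
    q_multi <- ((2 * v + 1) - sqrt((2 * v + 1)^2 - 4 * v^2)) / (2 * v)
  }
  structure(list(mu = mu, p_multistep = p_multistep,
                 variance_target = variance_target, q_multi = q_multi),
            class = "mutation_model")
}

#' @rdname mutation_model
#' @export
tpm80 <- function(mu = 1e-4, variance_target = 30) {
  mutation_model(mu, p_multistep = 0.2, variance_target = variance_target)
}

#' @export
print.mutation_model <- function(x, ...) {
  law <- if (x$q_multi < 0) "GSM (geometric step law)" else
    sprintf("TPM (multistep variance %.3g)", x$variance_target)
  cat(sprintf("Mutation model: mu = %g, p_multistep = %g, %s\n",
              x$mu, x$p_multistep, law))
  invisible(x)
}

# Internal: demography as the 9-column row layout the C++ batch code expects.
demog_row <- function(demography, mut) {
  st <- demography$start_time
  ne <- demography$ne
  n_ep <- length(ne)
  if (n_ep > 3) stop("batched simulation supports at most 3 epochs")
  c(n_ep,
    ne[1], if (n_ep >= 2) ne[2] else 0, if (n_ep >= 3) ne[3] else 0,
    if (n_ep >= 2) st[2] else 0, if (n_ep >= 3) st[3] else 0,
    mut$mu, mut$p_multistep, mut$q_multi)
}
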