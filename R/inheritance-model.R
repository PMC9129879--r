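#' Parameters of the histone-mark persistence model
#'
#' Describes the fate of a chromatin mark (e.g. H3K4me2) at a locus after
#' its deposition stops. Each DNA replication randomly segregates marked
#' nucleosomes between the daughter molecules, halving the marked fraction;
#' a reader-writer maintenance loop re-marks a newly diluted position with
#' probability `maintenance_prob` per division, and an active demethylase
#' removes the mark at rate `removal_rate` per minute. The marked fraction
#' follows `f(t) = ((1 + m)/2)^(t / T_d) * exp(-k t)`, so `m = 0, k = 0`
#' gives the pure replication-dilution expectation with half-life equal to
#' the doubling time, and `m = 1, k = 0` gives perfect inheritance.
#'
#' @param s0 Initial mark signal above background (ChIP recovery units,
#'   >= 0).
#' @param background Baseline signal in the same units (e.g. the recovery of
#'   a negative-control locus), >= 0.
#' @param doubling_time Culture doubling time T_d in minutes (> 0).
#' @param maintenance_prob Per-division probability m in `[0, 1]` that a
#'   position which lost its mark at replication is re-marked.
#' @param removal_rate Active removal rate k in per-minute units (>= 0).
#' @return An object of class `mark_decay_params`.
#' @export
#' @examples
#' mark_decay_params(s0 = 10, doubling_time = 120, maintenance_prob = 0.9)
mark_decay_params <- function(s0, background = 0, doubling_time,
                              maintenance_prob = 0, removal_rate = 0) {
  if (!is.numeric(s0) || length(s0) != 1 || s0 < 0) {
    abort("`s0` must be a single nonnegative number")
  }
  if (!is.numeric(background) || length(background) != 1 || background < 0) {
    abort("`background` must be a single nonnegative number")
  }
  if (!is.numeric(doubling_time) || length(doubling_time) != 1 ||
    doubling_time <= 0) {
    abort("`doubling_time` must be a single positive number of minutes")
  }
  if (!is.numeric(maintenance_prob) || length(maintenance_prob) != 1 ||
    maintenance_prob < 0 || maintenance_prob > 1) {
    abort("`maintenance_prob` must be in [0, 1]")
  }
  if (!is.numeric(removal_rate) || length(removal_rate) != 1 ||
    removal_rate < 0) {
    abort("`removal_rate` must be >= 0 (per minute)")
  }
  structure(
    list(
      s0 = s0, background = background, doubling_time = doubling_time,
      maintenance_prob = maintenance_prob, removal_rate = removal_rate
    ),
    class = "mark_decay_params"
  )
}

#' @export
print.mark_decay_params <- function(x, ...) {
  cat(sprintf(
    "<mark_decay_params> s0 = %.3g, background = %.3g, T_d = %.0f min, m = %.3f, k = %.4g /min (half-life %.1f min)\n",
    x$s0, x$background, x$doubling_time, x$maintenance_prob, x$removal_rate,
    half_life(x)
  ))
  invisible(x)
}

# net exponential decay rate (per minute) implied by (m, k)
decay_rate <- function(params) {
  log(2 / (1 + params$maintenance_prob)) / params$doubling_time +
    params$removal_rate
}

#' Fraction of nucleosomes still marked at time t
#'
#' `f(t) = ((1 + m)/2)^(t / T_d) * exp(-k t)`. With `m = 0, k = 0` this is
#' `2^(-t / T_d)` (pure dilution through DNA replication); with
#' `m = 1, k = 0` it is 1 for all t.
#'
#' @param params A [mark_decay_params()].
#' @param t Time in minutes (vectorized).
#' @return Marked fraction in `[0, 1]`.
#' @export
mark_fraction <- function(params, t) {
  stopifnot(inherits(params, "mark_decay_params"), all(t >= 0))
  exp(-decay_rate(params) * t)
}

#' Expected ChIP signal at time t
#'
#' `background + s0 * mark_fraction(params, t)`, assuming ChIP recovery is
#' linear in the marked-nucleosome fraction.
#'
#' @inheritParams mark_fraction
#' @return Expected signal (same units as `s0`/`background`).
#' @export
expected_signal <- function(params, t) {
  params$background + params$s0 * mark_fraction(params, t)
}

#' Half-life of the mark under the persistence model
#'
#' Time at which [mark_fraction()] reaches one half; equals the doubling
#' time when `m = 0, k = 0`, and is infinite for perfect inheritance.
#'
#' @param params A [mark_decay_params()].
#' @return Half-life in minutes (possibly `Inf`).
#' @export
half_life <- function(params) {
  lambda <- decay_rate(params)
  if (lambda <= 0) Inf else log(2) / lambda
}

#' Stochastic nucleosome-level simulation of mark inheritance
#'
#' Simulates a locus of `n_nucleosomes` positions through successive DNA
#' replications. At each division every marked nucleosome is retained with
#' probability 1/2 (random segregation into the two daughters); a position
#' that loses its mark is then re-marked with probability
#' `maintenance_prob` (the reader-writer loop copying from the retained
#' sister). The expected marked fraction after g divisions is
#' `((1 + m)/2)^g`, the discrete counterpart of [mark_fraction()].
#'
#' @param params A [mark_decay_params()] (only `maintenance_prob` is used;
#'   active removal is a continuous-time process outside this
#'   per-division simulator).
#' @param n_nucleosomes Number of nucleosome positions (>= 1).
#' @param n_divisions Number of replications to simulate.
#' @param seed Optional integer seed for reproducibility.
#' @return Tibble with columns `division` (0 .. n_divisions) and `fraction`
#'   (marked fraction; 1 at division 0).
#' @export
#' @examples
#' simulate_locus_divisions(
#'   mark_decay_params(1, doubling_time = 120, maintenance_prob = 0.5),
#'   n_nucleosomes = 1e4, n_divisions = 4, seed = 1
#' )
simulate_locus_divisions <- function(params, n_nucleosomes, n_divisions,
                                     seed = NULL) {
  stopifnot(
    inherits(params, "mark_decay_params"),
    n_nucleosomes >= 1, n_divisions >= 0
  )
  if (!is.null(seed)) set.seed(seed)
  m <- params$maintenance_prob
  marked <- rep(TRUE, n_nucleosomes)
  frac <- numeric(n_divisions + 1)
  frac[1] <- 1
  if (n_divisions > 0) {
    for (g in seq_len(n_divisions)) {
      retained <- marked & (runif(n_nucleosomes) < 0.5)
      lost <- marked & !retained
      remarked <- lost & (runif(n_nucleosomes) < m)
      marked <- retained | remarked
      frac[g + 1] <- mean(marked)
    }
  }
  tibble(division = 0:n_divisions, fraction = frac)
}
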