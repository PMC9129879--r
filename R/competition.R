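#' t0-normalized log2 abundance ratio of two competing strains
#'
#' The abundance ratio of strain A to strain B in a pooled sample with
#' A-fraction f is the odds f/(1-f). The competition readout is the log2
#' change in odds between the start of the competition and a later sample:
#' `log2((f_t/(1-f_t)) / (f_0/(1-f_0)))`. Normalizing by the t0 odds removes
#' any deviation from an exact 1:1 starting mix.
#'
#' @param fraction_t,fraction_0 Fractions of strain A at the endpoint and at
#'   t0, strictly inside (0, 1). Vectorized.
#' @return Numeric vector of log2 odds ratios.
#' @export
#' @examples
#' log2_abundance_ratio(2 / 3, 0.5) # odds doubled -> 1
log2_abundance_ratio <- function(fraction_t, fraction_0) {
  f <- c(fraction_t, fraction_0)
  if (any(!is.finite(f)) || any(f <= 0) || any(f >= 1)) {
    abort(
      "fractions must lie strictly inside (0, 1): a strain at 0 or 1 is extinct/fixed at measurement resolution and its odds ratio is unbounded",
      class = "epimem_ratio_error"
    )
  }
  odds <- function(f) f / (1 - f)
  log2(odds(fraction_t) / odds(fraction_0))
}

#' Estimate competitive fitness from paired t0/endpoint allele fractions
#'
#' Each biological replicate contributes one t0 sample and one endpoint
#' sample; its fitness readout is the t0-normalized log2 odds ratio
#' ([log2_abundance_ratio()]). Replicates are summarized as mean +/- SEM.
#' When the culture doubling time is supplied, the mean is also expressed as
#' a selection coefficient per generation.
#'
#' @param samples Data frame with columns `replicate`, `timepoint` (minutes
#'   since mixing; each replicate must have exactly one `timepoint == 0` row
#'   and exactly one endpoint row, the endpoint time shared across
#'   replicates) and `fraction_primary` (calibrated strain-A fraction in
#'   (0, 1)).
#' @param doubling_time Optional culture doubling time in minutes; enables
#'   `selection_per_generation = mean_log2_ratio / (duration / doubling_time)`.
#' @return An object of class `competition_result`; see [tidy.competition_result()]
#'   and [glance.competition_result()].
#' @export
#' @examples
#' sim <- simulate_competition(selection_per_generation = 0.25, seed = 1)
#' estimate_fitness(sim, doubling_time = 120)
estimate_fitness <- function(samples, doubling_time = NULL) {
  check_columns(
    samples, c("replicate", "timepoint", "fraction_primary"), "samples"
  )
  samples <- as_tibble(samples)
  if (any(samples$timepoint < 0)) abort("timepoints must be >= 0")

  per_rep <- samples |>
    dplyr::group_by(replicate) |>
    dplyr::group_map(function(d, key) {
      t0 <- d$fraction_primary[d$timepoint == 0]
      end <- d[d$timepoint > 0, ]
      if (length(t0) != 1 || nrow(end) != 1) {
        abort(
          sprintf(
            "replicate %s must have exactly one t = 0 and one endpoint sample",
            as.character(key$replicate)
          ),
          class = "epimem_pairing_error"
        )
      }
      tibble(
        replicate = key$replicate,
        fraction_0 = t0,
        fraction_t = end$fraction_primary,
        duration = end$timepoint,
        log2_ratio = log2_abundance_ratio(end$fraction_primary, t0)
      )
    }) |>
    dplyr::bind_rows()

  duration <- unique(per_rep$duration)
  if (length(duration) != 1) {
    abort("all replicates must share the same endpoint timepoint",
      class = "epimem_pairing_error"
    )
  }
  n <- nrow(per_rep)
  mean_lr <- mean(per_rep$log2_ratio)
  sem <- if (n >= 2) sd(per_rep$log2_ratio) / sqrt(n) else NA_real_
  sel <- if (!is.null(doubling_time)) {
    stopifnot(doubling_time > 0)
    mean_lr / (duration / doubling_time)
  } else {
    NA_real_
  }
  structure(
    list(
      replicates = per_rep,
      mean_log2_ratio = mean_lr,
      sem = sem,
      n_replicates = n,
      duration = duration,
      doubling_time = if (is.null(doubling_time)) NA_real_ else doubling_time,
      selection_per_generation = sel
    ),
    class = "competition_result"
  )
}

#' @export
print.competition_result <- function(x, ...) {
  cat(sprintf(
    "<competition_result> %d replicates, %.0f min: mean log2 ratio = %.3f",
    x$n_replicates, x$duration, x$mean_log2_ratio
  ))
  if (!is.na(x$sem)) cat(sprintf(" +/- %.3f (SEM)", x$sem))
  cat("\n")
  if (!is.na(x$selection_per_generation)) {
    cat(sprintf(
      "  selection per generation: %.3f (%.2f generations elapsed)\n",
      x$selection_per_generation, x$duration / x$doubling_time
    ))
  }
  invisible(x)
}

#' Per-replicate competition readouts
#' @param x A `competition_result`.
#' @param ... Unused.
#' @return Tibble with one row per replicate: fractions at t0/endpoint and
#'   the log2 odds ratio.
#' @export
tidy.competition_result <- function(x, ...) x$replicates

#' One-row competition summary
#' @param x A `competition_result`.
#' @param ... Unused.
#' @return One-row tibble: `mean_log2_ratio`, `sem`, `n_replicates`,
#'   `duration`, `selection_per_generation`.
#' @export
glance.competition_result <- function(x, ...) {
  tibble(
    mean_log2_ratio = x$mean_log2_ratio,
    sem = x$sem,
    n_replicates = x$n_replicates,
    duration = x$duration,
    selection_per_generation = x$selection_per_generation
  )
}
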