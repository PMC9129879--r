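#' Random-localization baseline under the spherical-shell model
#'
#' Probability that a uniformly positioned locus in a spherical nucleus lies
#' within a peripheral shell whose thickness is `shell_fraction` of the
#' nuclear radius: `1 - (1 - f)^3`. At the default shell fraction of 0.1
#' this gives 0.271, the ~27%-of-cells baseline expected for a randomly
#' positioned gene scored against the nuclear envelope.
#'
#' @param shell_fraction Shell thickness as a fraction of the radius, in
#'   (0, 1].
#' @return Probability in (0, 1].
#' @export
#' @examples
#' peripheral_baseline_analytic(0.1) # 0.271
peripheral_baseline_analytic <- function(shell_fraction) {
  if (!is.numeric(shell_fraction) || any(shell_fraction <= 0) ||
    any(shell_fraction > 1)) {
    abort("`shell_fraction` must lie in (0, 1]")
  }
  1 - (1 - shell_fraction)^3
}

#' Monte-Carlo estimate of the peripheral baseline
#'
#' Samples points uniformly in a sphere of the given radius and reports the
#' fraction within `shell_width` of the surface, with its binomial standard
#' error. Cross-checks [peripheral_baseline_analytic()].
#'
#' @param radius Nuclear radius (length units).
#' @param shell_width Shell thickness, in (0, radius].
#' @param n_points Number of points to sample.
#' @param seed Optional integer seed.
#' @return One-row tibble: `estimate`, `se` (binomial), `n_points`.
#' @export
peripheral_baseline_mc <- function(radius = 1, shell_width = 0.1 * radius,
                                   n_points = 1e6, seed = NULL) {
  stopifnot(radius > 0, n_points >= 1)
  if (shell_width <= 0 || shell_width > radius) {
    abort("`shell_width` must lie in (0, radius]")
  }
  if (!is.null(seed)) set.seed(seed)
  # radial CDF of a uniform point in a sphere is (r/R)^3
  r <- radius * runif(n_points)^(1 / 3)
  p_hat <- mean(r >= radius - shell_width)
  tibble(
    estimate = p_hat,
    se = sqrt(p_hat * (1 - p_hat) / n_points),
    n_points = n_points
  )
}

#' Replicate-level enrichment test for peripheral localization
#'
#' Converts per-replicate counts to percentages of cells with the locus at
#' the nuclear periphery and runs a one-tailed t-test at the replicate level
#' (never on pooled cells): one-sample against the random-localization
#' baseline, or Welch two-sample against a second dataset (e.g. auxin
#' treated vs untreated with `alternative = "less"`).
#'
#' @param data Data frame with columns `n_cells` and `n_peripheral`
#'   (one row per biological replicate; at least 2 replicates).
#' @param baseline Baseline probability in (0, 1) to test against
#'   (one-sample form), e.g. [peripheral_baseline_analytic()].
#' @param comparison Second dataset with the same columns (two-sample form).
#'   Exactly one of `baseline`/`comparison` must be supplied.
#' @param alternative `"greater"` or `"less"`.
#' @return An object of class `enrichment_test`; `tidy()` returns the
#'   per-replicate percentages, `glance()` the mean +/- SEM and p-value.
#' @export
#' @examples
#' counts <- simulate_localization_counts(0.6, n_cells = 40, seed = 2)
#' enrichment_test(counts, baseline = peripheral_baseline_analytic(0.1))
enrichment_test <- function(data, baseline = NULL, comparison = NULL,
                            alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (is.null(baseline) == is.null(comparison)) {
    abort("supply exactly one of `baseline` or `comparison`")
  }
  pct <- function(d, what) {
    check_columns(d, c("n_cells", "n_peripheral"), what)
    if (any(d$n_cells < 1) || any(d$n_peripheral < 0) ||
      any(d$n_peripheral > d$n_cells)) {
      abort("counts must satisfy 0 <= n_peripheral <= n_cells, n_cells >= 1")
    }
    if (nrow(d) < 2) {
      abort("need at least 2 replicates per group",
        class = "epimem_replication_error"
      )
    }
    dplyr::mutate(as_tibble(d), percent = 100 * n_peripheral / n_cells)
  }
  a <- pct(data, "data")
  if (!is.null(baseline)) {
    if (!is.numeric(baseline) || length(baseline) != 1 ||
      baseline <= 0 || baseline >= 1) {
      abort("`baseline` must be a probability in (0, 1)")
    }
    test <- one_tailed_t(a$percent, mu = 100 * baseline,
      alternative = alternative)
    reps <- dplyr::mutate(a, group = "data")
  } else {
    b <- pct(comparison, "comparison")
    test <- one_tailed_t(a$percent, b$percent, alternative = alternative)
    reps <- dplyr::bind_rows(
      dplyr::mutate(a, group = "data"),
      dplyr::mutate(b, group = "comparison")
    )
  }
  summary <- tibble(
    mean_percent = mean(a$percent),
    sem_percent = sd(a$percent) / sqrt(nrow(a)),
    n_replicates = nrow(a),
    baseline_percent = if (is.null(baseline)) NA_real_ else 100 * baseline,
    statistic = test$statistic,
    df = test$df,
    p_value = test$p_value,
    alternative = alternative,
    method = test$method
  )
  structure(
    list(replicates = reps, summary = summary),
    class = "enrichment_test"
  )
}

#' @export
print.enrichment_test <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<enrichment_test> %.1f%% +/- %.1f%% (n = %d replicates), %s, alternative = %s: p = %.4g\n",
    s$mean_percent, s$sem_percent, s$n_replicates, s$method,
    s$alternative, s$p_value
  ))
  invisible(x)
}

#' Per-replicate peripheral percentages
#' @param x An `enrichment_test`.
#' @param ... Unused.
#' @return Tibble of replicates with their `percent` peripheral.
#' @export
tidy.enrichment_test <- function(x, ...) x$replicates

#' One-row enrichment summary
#' @param x An `enrichment_test`.
#' @param ... Unused.
#' @return One-row tibble with mean, SEM, test statistic and p-value.
#' @export
glance.enrichment_test <- function(x, ...) x$summary
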