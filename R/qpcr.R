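#' Relative expression from paired Ct values (delta-Ct)
#'
#' Expression of a target transcript relative to a reference transcript
#' measured in the same sample: `efficiency^(ct_reference - ct_target)`,
#' e.g. INO1 mRNA quantified relative to ACT1 mRNA.
#'
#' @param samples Data frame with columns `ct_target` and `ct_reference`
#'   (cycle thresholds, > 0) and optionally `efficiency` (overrides the
#'   argument per row).
#' @param efficiency Amplification efficiency per cycle, in (1, 2];
#'   default 2 (perfect doubling).
#' @return `samples` with an added `rel_expression` column.
#' @export
#' @examples
#' relative_expression(
#'   tibble::tibble(ct_target = 22, ct_reference = 25)
#' ) # 2^3 = 8
relative_expression <- function(samples, efficiency = 2) {
  check_columns(samples, c("ct_target", "ct_reference"), "samples")
  samples <- as_tibble(samples)
  eff <- if ("efficiency" %in% names(samples)) {
    samples$efficiency
  } else {
    rep(efficiency, nrow(samples))
  }
  if (any(samples$ct_target <= 0) || any(samples$ct_reference <= 0)) {
    abort("Ct values must be positive")
  }
  if (any(eff <= 1) || any(eff > 2)) {
    abort("amplification efficiency must lie in (1, 2]")
  }
  dplyr::mutate(
    samples,
    rel_expression = eff^(.data$ct_reference - .data$ct_target)
  )
}

#' ChIP recovery relative to input
#'
#' Fraction of input chromatin recovered in the immunoprecipitate:
#' `input_fraction * efficiency^(ct_input - ct_ip)`, where `input_fraction`
#' is the fraction of chromatin saved as the input sample.
#'
#' @param samples Data frame with columns `ct_ip` and `ct_input` (> 0),
#'   optionally `efficiency`.
#' @param input_fraction Fraction of chromatin kept as input, in (0, 1].
#' @inheritParams relative_expression
#' @return `samples` with an added `recovery` column.
#' @export
#' @examples
#' chip_recovery(
#'   tibble::tibble(ct_ip = 24, ct_input = 27),
#'   input_fraction = 0.01
#' ) # 0.01 * 2^3 = 0.08
chip_recovery <- function(samples, input_fraction, efficiency = 2) {
  check_columns(samples, c("ct_ip", "ct_input"), "samples")
  samples <- as_tibble(samples)
  if (!is.numeric(input_fraction) || length(input_fraction) != 1 ||
    input_fraction <= 0 || input_fraction > 1) {
    abort("`input_fraction` must be a single value in (0, 1]")
  }
  eff <- if ("efficiency" %in% names(samples)) {
    samples$efficiency
  } else {
    rep(efficiency, nrow(samples))
  }
  if (any(samples$ct_ip <= 0) || any(samples$ct_input <= 0)) {
    abort("Ct values must be positive")
  }
  if (any(eff <= 1) || any(eff > 2)) {
    abort("amplification efficiency must lie in (1, 2]")
  }
  dplyr::mutate(
    samples,
    recovery = input_fraction * eff^(.data$ct_input - .data$ct_ip)
  )
}

#' One-tailed t-test on biological replicates
#'
#' One-sample (against a null mean) or Welch two-sample t-test with a
#' one-sided alternative, the replicate-level test used throughout for
#' comparing conditions. Degenerate constant data (zero variance in every
#' group), which [stats::t.test()] refuses, is handled at the boundary:
#' t = 0 and p = 0.5 when the means are equal, p of 0 or 1 otherwise.
#'
#' @param x Numeric vector of replicate values (n >= 2).
#' @param y Optional second group for the two-sample form.
#' @param mu Null-hypothesis mean for the one-sample form.
#' @param alternative `"greater"` or `"less"` (one-tailed by design).
#' @return One-row tibble: `estimate` (mean of x, or mean difference),
#'   `statistic`, `df`, `p_value`, `alternative`, `method`.
#' @export
#' @examples
#' one_tailed_t(c(5, 6, 7), mu = 0, alternative = "greater")
one_tailed_t <- function(x, y = NULL, mu = NULL,
                         alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) < 2) {
    abort("need at least 2 replicates in `x`",
      class = "epimem_replication_error"
    )
  }
  if (is.null(y)) {
    if (is.null(mu)) abort("supply `y` (two-sample) or `mu` (one-sample)")
    method <- "one-sample t-test"
    estimate <- mean(x) - mu
    boundary <- sd(x) == 0
  } else {
    if (length(y) < 2) {
      abort("need at least 2 replicates in `y`",
        class = "epimem_replication_error"
      )
    }
    method <- "Welch two-sample t-test"
    estimate <- mean(x) - mean(y)
    boundary <- sd(x) == 0 && sd(y) == 0
  }
  if (boundary) {
    df <- if (is.null(y)) length(x) - 1 else length(x) + length(y) - 2
    statistic <- if (estimate == 0) 0 else sign(estimate) * Inf
    p <- pt(statistic, df, lower.tail = (alternative == "less"))
  } else {
    tt <- if (is.null(y)) {
      stats::t.test(x, mu = mu, alternative = alternative)
    } else {
      stats::t.test(x, y, alternative = alternative, var.equal = FALSE)
    }
    statistic <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p <- tt$p.value
  }
  tibble(
    estimate = estimate, statistic = statistic, df = df, p_value = p,
    alternative = alternative, method = method
  )
}
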