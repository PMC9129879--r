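# ggplot2 figures for each result type. Channel colours follow the usual
# chromatogram convention (A green, C blue, G black, T red).

trace_colours <- c(A = "#2e8b57", C = "#1e62c8", G = "#222222", T = "#c8321e")

#' Plot a chromatogram trace
#'
#' @param object A [trace_signal()].
#' @param window Optional integer vector `c(from, to)` of 0-based scan
#'   positions to restrict the plot to.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trace_signal <- function(object, window = NULL, ...) {
  d <- tidyr::pivot_longer(
    object$intensities, dplyr::all_of(trace_channels),
    names_to = "channel", values_to = "intensity"
  )
  if (!is.null(window)) {
    d <- dplyr::filter(d, pos >= window[1], pos <= window[2])
  }
  ggplot2::ggplot(d, ggplot2::aes(pos, intensity, colour = channel)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = trace_colours) +
    ggplot2::geom_vline(
      xintercept = object$basecalls$peak_pos,
      linetype = "dotted", colour = "grey70"
    ) +
    ggplot2::labs(
      x = "scan position", y = "fluorescence (a.u.)", colour = "channel"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a standard curve with its fit and the identity line
#'
#' @param object A [fit_standard_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot2::ggplot(
    object$data,
    ggplot2::aes(true_fraction, measured_fraction)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
      colour = "grey60") +
    ggplot2::geom_abline(
      slope = object$slope, intercept = object$intercept, colour = "#1e62c8"
    ) +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "designed fraction (true mix)",
      y = "measured fraction (peak areas)",
      title = sprintf(
        "slope %.3f, intercept %.3f, r² %.3f",
        object$slope, object$intercept, object$r_squared
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-replicate competition readouts with their mean
#'
#' @param object A [estimate_fitness()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.competition_result <- function(object, ...) {
  d <- object$replicates
  ggplot2::ggplot(d, ggplot2::aes(x = "competition", y = log2_ratio)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.05),
      alpha = 0.8) +
    ggplot2::annotate(
      "pointrange",
      x = "competition",
      y = object$mean_log2_ratio,
      ymin = object$mean_log2_ratio - ifelse(is.na(object$sem), 0, object$sem),
      ymax = object$mean_log2_ratio + ifelse(is.na(object$sem), 0, object$sem),
      colour = "#c8321e"
    ) +
    ggplot2::labs(x = NULL, y = "log2 abundance ratio (t / t0)") +
    ggplot2::theme_minimal()
}

#' Plot a fitted mark-decay time course
#'
#' Shows the data (points with SEM bars), the fitted curve, the pure
#' replication-dilution expectation (dashed: half-life equal to the doubling
#' time), and alternating shading for successive generations.
#'
#' @param object A [fit_decay()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mark_decay_fit <- function(object, ...) {
  d <- object$data
  p <- object$params
  tt <- seq(min(d$time), max(d$time), length.out = 200)
  curve <- tibble(time = tt, fitted = expected_signal(p, tt))
  dil <- mark_decay_params(p$s0, p$background, p$doubling_time)
  dashed <- tibble(time = tt, fitted = expected_signal(dil, tt))
  gens <- tibble(
    xmin = seq(0, max(d$time), by = p$doubling_time)
  ) |>
    dplyr::mutate(xmax = pmin(xmin + p$doubling_time, max(d$time)))
  gens <- gens[seq(1, nrow(gens), by = 2), ]
  g <- ggplot2::ggplot(d, ggplot2::aes(time, signal))
  if (nrow(gens) > 0) {
    g <- g + ggplot2::geom_rect(
      data = gens,
      ggplot2::aes(xmin = xmin, xmax = xmax, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey92"
    )
  }
  if ("sem" %in% names(d)) {
    g <- g + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = signal - sem, ymax = signal + sem),
      width = 0.02 * max(d$time)
    )
  }
  g +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = dashed, ggplot2::aes(time, fitted),
      linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line(data = curve, ggplot2::aes(time, fitted),
      colour = "#1e62c8") +
    ggplot2::labs(
      x = "time after repression (min)", y = "ChIP recovery",
      title = sprintf(
        "%s: m = %.2f, k = %.3g /min, half-life %.0f min",
        object$model, p$maintenance_prob, p$removal_rate, object$half_life
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot replicate peripheral-localization percentages
#'
#' @param data Data frame of replicate counts (`n_cells`, `n_peripheral`,
#'   optionally `condition`).
#' @param baseline Optional baseline probability drawn as a dashed line
#'   (e.g. [peripheral_baseline_analytic()]).
#' @return A ggplot.
#' @export
plot_localization <- function(data, baseline = NULL) {
  check_columns(data, c("n_cells", "n_peripheral"), "data")
  d <- dplyr::mutate(
    as_tibble(data),
    percent = 100 * n_peripheral / n_cells,
    condition = if ("condition" %in% names(data)) condition else "data"
  )
  g <- ggplot2::ggplot(d, ggplot2::aes(condition, percent)) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.08)) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
      colour = "#1e62c8") +
    ggplot2::labs(x = NULL, y = "% cells with locus at periphery") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
  if (!is.null(baseline)) {
    g <- g + ggplot2::geom_hline(
      yintercept = 100 * baseline, linetype = "dashed", colour = "#1e62c8"
    )
  }
  g
}
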