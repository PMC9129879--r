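#' Locate the SNP basecall in a trace
#'
#' Searches the called-base sequence for the locus context
#' `flank_left ? flank_right`, where `?` matches any base (the SNP position).
#' Exactly one match is required.
#'
#' @param trace A [trace_signal()].
#' @param locus A [snp_locus()].
#' @return The 0-based basecall index of the SNP position.
#' @export
#' @examples
#' tr <- simulate_trace("TTGGAACCATT", snp_index = 5, fraction_primary = 0.75)
#' locate_snp_peak(tr, snp_locus("A", "C", "TTGGA", "CCATT"))
locate_snp_peak <- function(trace, locus) {
  stopifnot(inherits(trace, "trace_signal"), inherits(locus, "snp_locus"))
  seq <- called_sequence(trace)
  pattern <- paste0(locus$flank_left, "[ACGTN]", locus$flank_right)
  m <- gregexpr(pattern, seq)[[1]]
  n_hit <- if (m[1] == -1) 0L else length(m)
  if (n_hit == 0) {
    abort(
      sprintf(
        "locus not found: context %s?%s absent from called bases",
        locus$flank_left, locus$flank_right
      ),
      class = "epimem_locus_error"
    )
  }
  if (n_hit > 1) {
    abort(
      sprintf("ambiguous locus: context matches at %d positions", n_hit),
      class = "epimem_locus_error"
    )
  }
  # 0-based index of the wildcard position
  as.integer(m[1] - 1L + nchar(locus$flank_left))
}

# integration window around basecall i (0-based): from the midpoint to the
# previous peak up to (exclusive) the midpoint to the next peak; trace ends
# clamp to [0, L)
snp_window <- function(trace, snp_index) {
  bc <- trace$basecalls
  i <- snp_index + 1L # row
  if (snp_index < 0 || snp_index >= nrow(bc)) {
    abort(sprintf("snp_index %d out of range", snp_index))
  }
  p <- bc$peak_pos[i]
  lo <- if (i == 1L) 0L else as.integer(floor((bc$peak_pos[i - 1L] + p) / 2))
  hi <- if (i == nrow(bc)) {
    trace_length(trace)
  } else {
    as.integer(floor((p + bc$peak_pos[i + 1L]) / 2))
  }
  c(lo = lo, hi = hi) # scans lo .. hi-1
}

#' Quantify relative allele abundance from peak areas
#'
#' Integrates the two allele channels over the SNP peak's window (from the
#' midpoint to the neighbouring peak on each side, clamped at the trace
#' ends), after subtracting each channel's within-window minimum as a
#' baseline, and reports the area fraction of the primary allele.
#'
#' @param trace A [trace_signal()].
#' @param locus A [snp_locus()] naming the two allele channels.
#' @param snp_index 0-based basecall index of the SNP; located via
#'   [locate_snp_peak()] when omitted.
#' @return One-row tibble with columns `snp_index`, `area_primary`,
#'   `area_secondary`, `fraction_primary`.
#' @export
#' @examples
#' tr <- simulate_trace("TTGGAACCATT", snp_index = 5, fraction_primary = 0.75)
#' quantify_allele_fraction(tr, snp_locus("A", "C", "TTGGA", "CCATT"))
quantify_allele_fraction <- function(trace, locus, snp_index = NULL) {
  stopifnot(inherits(trace, "trace_signal"), inherits(locus, "snp_locus"))
  if (is.null(snp_index)) snp_index <- locate_snp_peak(trace, locus)
  w <- snp_window(trace, snp_index)
  rows <- (w[["lo"]] + 1L):w[["hi"]]
  area_of <- function(channel) {
    v <- trace$intensities[[channel]][rows]
    sum(v - min(v))
  }
  area_p <- area_of(locus$allele_primary)
  area_s <- area_of(locus$allele_secondary)
  if (area_p + area_s <= 0) {
    abort(
      "degenerate signal: both allele channels have zero baseline-corrected area in the SNP window",
      class = "epimem_signal_error"
    )
  }
  tibble(
    snp_index = as.integer(snp_index),
    area_primary = area_p,
    area_secondary = area_s,
    fraction_primary = area_p / (area_p + area_s)
  )
}

#' Fit a linear standard curve of measured on true mixture fraction
#'
#' Ordinary least squares of the measured allele fraction on the designed
#' (true) mixture fraction, as in a calibration series where two strains are
#' mixed at known proportions and quantified from chromatogram peak areas.
#'
#' @param pairs Data frame with columns `true_fraction` and
#'   `measured_fraction`, both in `[0, 1]`, at least two distinct true
#'   fractions.
#' @return An object of class `standard_curve` with elements `data`, `fit`
#'   (the `lm`), `slope`, `intercept`, `r_squared`.
#' @export
#' @examples
#' design <- c(0, .05, .25, .40, .50, .60, .75, .90, 1)
#' fit_standard_curve(
#'   tibble::tibble(true_fraction = design, measured_fraction = design)
#' )
fit_standard_curve <- function(pairs) {
  check_columns(pairs, c("true_fraction", "measured_fraction"), "pairs")
  pairs <- as_tibble(pairs)
  if (nrow(pairs) < 2 || length(unique(pairs$true_fraction)) < 2) {
    abort(
      "standard curve needs at least two distinct true fractions (design is rank deficient)",
      class = "epimem_curve_error"
    )
  }
  fit <- lm(measured_fraction ~ true_fraction, data = pairs)
  s <- suppressWarnings(summary(fit))
  structure(
    list(
      data = pairs,
      fit = fit,
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = s$r.squared
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> measured = %.4f * true + %.4f  (r^2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, nrow(x$data)
  ))
  invisible(x)
}

#' @export
tidy.standard_curve <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble(
    term = c("intercept", "slope"),
    estimate = unname(s[, "Estimate"]),
    std_error = unname(s[, "Std. Error"])
  )
}

#' @export
glance.standard_curve <- function(x, ...) {
  tibble(
    slope = x$slope, intercept = x$intercept,
    r_squared = x$r_squared, n = nrow(x$data)
  )
}

#' Invert a standard curve to calibrate measured fractions
#'
#' Maps a measured fraction back to the true-mixture scale via
#' `(measured - intercept) / slope`, clamped to `[0, 1]`; clamping is
#' reported in the `clamped` column.
#'
#' @param curve A [fit_standard_curve()] result with positive slope.
#' @param measured Numeric vector of measured fractions.
#' @return Tibble with columns `measured`, `calibrated`, `clamped`.
#' @export
calibrate_fraction <- function(curve, measured) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!is.finite(curve$slope) || curve$slope <= 0) {
    abort("unusable standard curve: slope must be positive",
      class = "epimem_curve_error"
    )
  }
  raw <- (measured - curve$intercept) / curve$slope
  cal <- pmin(1, pmax(0, raw))
  tibble(measured = measured, calibrated = cal, clamped = raw != cal)
}
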