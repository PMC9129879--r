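# Synthetic-data generators. Each one is deterministic under `seed` and
# attaches the generating ground truth as the "ground_truth" attribute so
# downstream estimates can be scored without peeking at the data files.

#' Simulate a four-channel chromatogram trace with a biallelic SNP
#'
#' Each called base contributes a Gaussian peak in its channel; at the SNP
#' position the two allele channels receive amplitudes proportional to
#' `fraction_primary` and `1 - fraction_primary`. Noise is multiplicative on
#' peak heights (assay noise scales with signal) and a constant additive
#' baseline can be included.
#'
#' @param sequence Called-base string (A/C/G/T); the character at
#'   `snp_index` is replaced by the majority allele in the output calls.
#' @param snp_index 0-based index of the SNP within `sequence`.
#' @param fraction_primary True fraction of the primary allele in `[0, 1]`.
#' @param allele_primary,allele_secondary The two allele bases (default A/C).
#' @param spacing Scans per base (peak-to-peak distance).
#' @param peak_width Gaussian peak sd in scan units. A warning is issued
#'   when `spacing <= 4 * peak_width` (peaks overlap substantially).
#' @param amplitude Peak height in fluorescence units.
#' @param noise_sd Multiplicative Gaussian noise sd on each peak height
#'   (0.05 = 5%).
#' @param baseline Additive constant baseline intensity.
#' @param seed Optional integer seed.
#' @return A [trace_signal()] with attribute `ground_truth` (list with the
#'   SNP basecall index, the true fraction and the realized allele peak
#'   parameters).
#' @export
#' @examples
#' tr <- simulate_trace("TTGGAACCATT", 5, 0.75, noise_sd = 0.05, seed = 1)
#' attr(tr, "ground_truth")$fraction_primary
simulate_trace <- function(sequence, snp_index, fraction_primary,
                           allele_primary = "A", allele_secondary = "C",
                           spacing = 10, peak_width = 2, amplitude = 100,
                           noise_sd = 0, baseline = 0, seed = NULL) {
  stopifnot(
    is.character(sequence), length(sequence) == 1,
    fraction_primary >= 0, fraction_primary <= 1,
    spacing >= 2, peak_width > 0, amplitude > 0, baseline >= 0, noise_sd >= 0
  )
  bases <- strsplit(toupper(sequence), "")[[1]]
  n <- length(bases)
  if (snp_index < 0 || snp_index >= n) abort("`snp_index` out of range")
  if (!all(bases[-(snp_index + 1)] %in% trace_channels)) {
    abort("`sequence` must contain only A, C, G, T outside the SNP position")
  }
  if (spacing <= 4 * peak_width) {
    warn("peak spacing <= 4 * peak_width: neighbouring peaks overlap substantially")
  }
  if (!is.null(seed)) set.seed(seed)

  centers <- (0:(n - 1)) * spacing + spacing / 2
  L <- n * spacing
  scans <- 0:(L - 1)
  noisy <- function(a) max(0, a * (1 + rnorm(1, 0, noise_sd)))

  # peak list: one per non-SNP base, two allele peaks at the SNP
  channels <- setNames(
    lapply(trace_channels, function(ch) rep(baseline, L)), trace_channels
  )
  add_peak <- function(channels, ch, center, amp) {
    channels[[ch]] <- channels[[ch]] +
      amp * exp(-(scans - center)^2 / (2 * peak_width^2))
    channels
  }
  amp_primary <- amp_secondary <- NA_real_
  for (j in seq_len(n)) {
    if (j == snp_index + 1) {
      amp_primary <- noisy(amplitude * fraction_primary)
      amp_secondary <- noisy(amplitude * (1 - fraction_primary))
      channels <- add_peak(channels, allele_primary, centers[j], amp_primary)
      channels <- add_peak(channels, allele_secondary, centers[j], amp_secondary)
    } else {
      channels <- add_peak(channels, bases[j], centers[j], noisy(amplitude))
    }
  }
  called <- bases
  called[snp_index + 1] <- if (fraction_primary >= 0.5) {
    allele_primary
  } else {
    allele_secondary
  }
  tr <- trace_signal(
    intensities = tibble(
      pos = as.integer(scans),
      A = channels$A, C = channels$C, G = channels$G, T = channels$T
    ),
    basecalls = tibble(
      index = 0:(n - 1),
      base = called,
      peak_pos = as.integer(round(centers))
    )
  )
  attr(tr, "ground_truth") <- list(
    snp_index = as.integer(snp_index),
    fraction_primary = fraction_primary,
    allele_primary = allele_primary,
    allele_secondary = allele_secondary,
    amp_primary = amp_primary,
    amp_secondary = amp_secondary,
    peak_width = peak_width,
    center = centers[snp_index + 1],
    spacing = spacing,
    baseline = baseline
  )
  tr
}

#' Simulate a two-strain exponential-growth competition
#'
#' Both strains grow exponentially from a known starting mix; the true
#' strain-A fraction at each sampling time follows from the growth rates,
#' and measured fractions add Gaussian assay noise (clamped to the open unit
#' interval). Strain A's advantage can be given as a selection coefficient
#' per generation (log2 odds gained per doubling of strain B).
#'
#' @param initial_fraction Strain-A fraction at mixing (default 0.5, a 1:1
#'   start).
#' @param selection_per_generation Selection coefficient s: strain A's
#'   growth rate is `(1 + s) * log(2) / doubling_time`. Ignored when both
#'   explicit growth rates are supplied.
#' @param growth_rate_a,growth_rate_b Optional explicit per-minute growth
#'   rates (> 0).
#' @param duration Competition length in minutes (default 180, i.e. 3 hr).
#' @param doubling_time Reference doubling time in minutes (default 120).
#' @param noise_sd Additive Gaussian assay noise sd on the measured fraction
#'   (default 0.02).
#' @param n_replicates Number of biological replicates.
#' @param seed Optional integer seed.
#' @return Tibble with columns `replicate`, `timepoint`, `fraction_true`,
#'   `fraction_primary` (measured), ready for [estimate_fitness()];
#'   attribute `ground_truth` records the rates and the expected log2 odds
#'   ratio.
#' @export
#' @examples
#' simulate_competition(selection_per_generation = 0.5, seed = 1)
simulate_competition <- function(initial_fraction = 0.5,
                                 selection_per_generation = 0,
                                 growth_rate_a = NULL, growth_rate_b = NULL,
                                 duration = 180, doubling_time = 120,
                                 noise_sd = 0.02, n_replicates = 3,
                                 seed = NULL) {
  stopifnot(
    initial_fraction > 0, initial_fraction < 1,
    duration >= 0, doubling_time > 0, noise_sd >= 0, n_replicates >= 1
  )
  if (!is.null(seed)) set.seed(seed)
  r_b <- if (is.null(growth_rate_b)) log(2) / doubling_time else growth_rate_b
  r_a <- if (is.null(growth_rate_a)) {
    (1 + selection_per_generation) * log(2) / doubling_time
  } else {
    growth_rate_a
  }
  stopifnot(r_a > 0, r_b > 0)
  true_frac <- function(t) {
    na <- initial_fraction * exp(r_a * t)
    nb <- (1 - initial_fraction) * exp(r_b * t)
    na / (na + nb)
  }
  timepoints <- c(0, duration)
  eps <- 1e-9
  out <- tidyr::expand_grid(
    replicate = seq_len(n_replicates),
    timepoint = timepoints
  ) |>
    dplyr::mutate(
      fraction_true = true_frac(timepoint),
      fraction_primary = pmin(
        1 - eps,
        pmax(eps, fraction_true + rnorm(dplyr::n(), 0, noise_sd))
      )
    )
  attr(out, "ground_truth") <- list(
    growth_rate_a = r_a, growth_rate_b = r_b,
    initial_fraction = initial_fraction,
    duration = duration, doubling_time = doubling_time,
    expected_log2_ratio = (r_a - r_b) * duration / log(2)
  )
  out
}

#' Simulate a ChIP-qPCR decay time course
#'
#' Replicate signals are drawn around [expected_signal()] with
#' multiplicative Gaussian noise, then summarized as mean and SEM per
#' timepoint — the shape of a ChIP time course after deposition of the mark
#' stops.
#'
#' @param params A [mark_decay_params()] giving the generating regime.
#' @param timepoints Sampling times in minutes, strictly increasing.
#' @param noise_sd Multiplicative noise sd on each replicate signal
#'   (default 0.05).
#' @param n_replicates Replicates per timepoint (default 3).
#' @param seed Optional integer seed.
#' @param locus Locus label carried through.
#' @param control_level Level of the negative-control locus measured
#'   alongside the target (as ChIP-qPCR experiments always do); defaults to
#'   the generating background. Drawn with the same multiplicative noise and
#'   reported in a `control` column. Set to `NULL` to omit.
#' @return Tibble with columns `time`, `signal` (replicate mean), `sem`,
#'   `n`, `control` (unless omitted), `locus`; attributes `ground_truth`
#'   (the params) and `replicates` (the replicate-level draws).
#' @export
#' @examples
#' truth <- mark_decay_params(10, 1, 120, maintenance_prob = 0.9)
#' simulate_chip_timecourse(truth, seq(0, 480, 96), seed = 1)
simulate_chip_timecourse <- function(params, timepoints, noise_sd = 0.05,
                                     n_replicates = 3, seed = NULL,
                                     locus = "locus",
                                     control_level = params$background) {
  stopifnot(
    inherits(params, "mark_decay_params"),
    all(timepoints >= 0), !is.unsorted(timepoints, strictly = TRUE),
    noise_sd >= 0, n_replicates >= 1
  )
  if (!is.null(seed)) set.seed(seed)
  reps <- tidyr::expand_grid(
    time = timepoints,
    replicate = seq_len(n_replicates)
  ) |>
    dplyr::mutate(
      expected = expected_signal(params, time),
      signal = pmax(0, expected * (1 + rnorm(dplyr::n(), 0, noise_sd)))
    )
  if (!is.null(control_level)) {
    stopifnot(control_level >= 0)
    reps$control <- pmax(
      0, control_level * (1 + rnorm(nrow(reps), 0, noise_sd))
    )
  }
  out <- reps |>
    dplyr::group_by(time) |>
    dplyr::summarise(
      sem = if (dplyr::n() >= 2) sd(signal) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(),
      dplyr::across(dplyr::any_of("control"), mean),
      signal = mean(signal),
      .groups = "drop"
    ) |>
    dplyr::select(
      time, signal, sem, n, dplyr::any_of("control")
    ) |>
    dplyr::mutate(locus = locus)
  attr(out, "ground_truth") <- params
  attr(out, "replicates") <- reps
  out
}

#' Simulate replicate localization counts
#'
#' Binomial draws of peripheral cells per biological replicate at a given
#' true peripheral probability.
#'
#' @param p True probability a cell scores peripheral.
#' @param n_cells Cells scored per replicate (the scoring convention is at
#'   least 30).
#' @param n_replicates Number of biological replicates.
#' @param condition,timepoint Labels carried through.
#' @param seed Optional integer seed.
#' @return Tibble with columns `condition`, `timepoint`, `replicate`,
#'   `n_cells`, `n_peripheral`, suitable for [enrichment_test()].
#' @export
simulate_localization_counts <- function(p, n_cells = 30, n_replicates = 3,
                                         condition = "condition",
                                         timepoint = 0, seed = NULL) {
  stopifnot(p >= 0, p <= 1, n_cells >= 1, n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  tibble(
    condition = condition,
    timepoint = timepoint,
    replicate = seq_len(n_replicates),
    n_cells = as.integer(n_cells),
    n_peripheral = rbinom(n_replicates, n_cells, p)
  )
}
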