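#' Write a reproducible fixture suite for every assay
#'
#' Emits, under `out_dir`: one calibration trace per design fraction of the
#' nine-point mixing series (0, 5, 25, 40, 50, 60, 75, 90, 100% primary
#' allele) plus the SNP locus descriptor; a 1:1-start, 3-hr competition
#' table; ChIP decay time courses for the three persistence regimes
#' (passive dilution, maintained, actively removed; doubling time 120 min);
#' and localization counts at the random baseline and at an enriched
#' probability. Ground truth goes into a sidecar `manifest.tsv` (never into
#' the data files themselves), together with an md5 checksum per file.
#'
#' @param seed Integer seed; the whole suite is deterministic given it.
#' @param out_dir Output directory (created if needed).
#' @return The manifest as a tibble (columns `file`, `kind`, `truth`,
#'   `md5`), invisibly; also written to `manifest.tsv`.
#' @export
make_fixture_suite <- function(seed, out_dir) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  add <- function(file, kind, truth) {
    rows[[length(rows) + 1]] <<- tibble(file = file, kind = kind, truth = truth)
  }
  # flanks end/start in G/T so neither allele channel (A or C) has a
  # neighbouring peak bleeding into the SNP integration window
  locus <- snp_locus("A", "C", "TTGGT", "GTCTT", label = "fixture SNP")
  sequence <- paste0("GTCA", "TTGGT", "A", "GTCTT", "ACGT")
  snp_idx <- 9L

  write_snp_locus(locus, file.path(out_dir, "locus.tsv"))
  add("locus.tsv", "snp_locus", "A/C SNP, flanks TTGGA/CCATT")

  design <- c(0, 0.05, 0.25, 0.40, 0.50, 0.60, 0.75, 0.90, 1.0)
  for (i in seq_along(design)) {
    f <- design[i]
    tr <- simulate_trace(
      sequence, snp_idx, f,
      noise_sd = 0.05, seed = seed + i
    )
    file <- sprintf("trace_frac%03.0f.tsv", 100 * f)
    write_trace(tr, file.path(out_dir, file))
    add(file, "calibration_trace", sprintf("fraction_primary=%.2f", f))
  }

  comp <- simulate_competition(
    initial_fraction = 0.5, selection_per_generation = 0,
    duration = 180, doubling_time = 120, seed = seed + 100
  )
  readr::write_tsv(comp, file.path(out_dir, "competition.tsv"))
  add(
    "competition.tsv", "competition",
    "1:1 start, equal growth rates, 180 min, expected log2 ratio 0"
  )

  times <- seq(0, 480, by = 96)
  regimes <- list(
    passive = mark_decay_params(10, 1, 120),
    maintained = mark_decay_params(10, 1, 120, maintenance_prob = 0.9),
    active_removal = mark_decay_params(10, 1, 120, removal_rate = 0.03)
  )
  for (nm in names(regimes)) {
    tc <- simulate_chip_timecourse(
      regimes[[nm]], times,
      noise_sd = 0.05, seed = seed + 200 + match(nm, names(regimes))
    )
    file <- sprintf("chip_%s.tsv", nm)
    readr::write_tsv(tc, file.path(out_dir, file))
    p <- regimes[[nm]]
    add(file, "chip_timecourse", sprintf(
      "s0=%g background=%g T_d=%g m=%g k=%g",
      p$s0, p$background, p$doubling_time, p$maintenance_prob, p$removal_rate
    ))
  }

  for (p_true in c(
    baseline = peripheral_baseline_analytic(0.1),
    enriched = 0.6
  )) {
    nm <- if (p_true > 0.5) "enriched" else "baseline"
    counts <- simulate_localization_counts(
      p_true,
      n_cells = 30, n_replicates = 3,
      condition = nm, seed = seed + 300 + (p_true > 0.5)
    )
    file <- sprintf("localization_%s.tsv", nm)
    readr::write_tsv(counts, file.path(out_dir, file))
    add(file, "localization_counts", sprintf("p=%.4f n_cells=30", p_true))
  }

  manifest <- dplyr::bind_rows(rows)
  manifest$md5 <- unname(tools::md5sum(file.path(out_dir, manifest$file)))
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}
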