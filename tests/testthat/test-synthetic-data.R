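test_that("trace generator respects its contract", {
  # pure primary allele: secondary channel flat at baseline in the window
  pure <- make_quant_trace(1.0, baseline = 1)
  gt <- attr(pure, "ground_truth")
  win <- (gt$center - 5):(gt$center + 4) + 1
  expect_equal(pure$intensities$C[win], rep(1, 10))

  # 50:50 mix without noise: allele areas equal to within 0.1%
  even <- make_quant_trace(0.5)
  q <- quantify_allele_fraction(even, quant_locus)
  expect_equal(q$area_primary / q$area_secondary, 1, tolerance = 0.001)

  # determinism under a fixed seed
  a <- make_quant_trace(0.3, noise_sd = 0.05, seed = 7)
  b <- make_quant_trace(0.3, noise_sd = 0.05, seed = 7)
  expect_identical(a$intensities, b$intensities)
  expect_identical(a$basecalls, b$basecalls)

  # generated traces satisfy the trace invariants and survive a round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(a, path)
  expect_equal(read_trace(path)$intensities, a$intensities)

  expect_warning(
    simulate_trace("ACGT", 1, 0.5, spacing = 6, peak_width = 2),
    "overlap"
  )
})

test_that("competition generator produces paired samples with exact truth", {
  # equal growth rates, no noise: fraction constant
  null <- simulate_competition(noise_sd = 0, n_replicates = 2)
  expect_equal(unique(null$fraction_true), 0.5)
  expect_equal(null$fraction_primary, null$fraction_true)

  # one extra doubling of strain A over the duration: end fraction 2/3
  adv <- simulate_competition(
    growth_rate_a = log(2) / 120 + log(2) / 180,
    growth_rate_b = log(2) / 120,
    duration = 180, noise_sd = 0, n_replicates = 1
  )
  expect_equal(adv$fraction_true[adv$timepoint == 180], 2 / 3)
  expect_equal(attr(adv, "ground_truth")$expected_log2_ratio, 1)

  # bookkeeping: 3 replicates -> 6 rows (t0 + endpoint each)
  three <- simulate_competition(n_replicates = 3, seed = 1)
  expect_equal(nrow(three), 6L)
  expect_equal(sum(three$timepoint == 0), 3L)

  expect_identical(
    simulate_competition(seed = 12)$fraction_primary,
    simulate_competition(seed = 12)$fraction_primary
  )
})

test_that("chip time-course generator sits on the expected curve", {
  p <- mark_decay_params(10, 1, 120)
  noise_free <- simulate_chip_timecourse(p, seq(0, 480, 96), noise_sd = 0)
  expect_equal(noise_free$signal, expected_signal(p, noise_free$time))
  # at t = T_d the dilution-only signal is background + s0/2
  at_td <- simulate_chip_timecourse(p, c(0, 120), noise_sd = 0)
  expect_equal(at_td$signal[2], 1 + 10 / 2)
  # control column tracks the background level
  expect_equal(noise_free$control, rep(1, 6))

  a <- simulate_chip_timecourse(p, seq(0, 480, 96), seed = 5)
  b <- simulate_chip_timecourse(p, seq(0, 480, 96), seed = 5)
  expect_identical(a, b)

  no_ctrl <- simulate_chip_timecourse(
    p, seq(0, 480, 96),
    seed = 5, control_level = NULL
  )
  expect_false("control" %in% names(no_ctrl))
})

test_that("localization counts are binomial draws with the right mean", {
  all_in <- simulate_localization_counts(1, n_cells = 30, n_replicates = 4)
  expect_equal(all_in$n_peripheral, rep(30L, 4))

  big <- simulate_localization_counts(
    0.27,
    n_cells = 30, n_replicates = 2000, seed = 9
  )
  se <- sqrt(0.27 * 0.73 / (30 * 2000))
  expect_lt(abs(mean(big$n_peripheral / big$n_cells) - 0.27), 3 * se)

  expect_identical(
    simulate_localization_counts(0.3, seed = 2),
    simulate_localization_counts(0.3, seed = 2)
  )
})

test_that("fixture suite is complete, deterministic and ground-truthed", {
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  man_a <- make_fixture_suite(101, dir_a)
  man_b <- make_fixture_suite(101, dir_b)

  # one calibration trace per design fraction in the nine-point mixing series
  traces <- man_a$file[man_a$kind == "calibration_trace"]
  expect_length(traces, 9L)
  expect_identical(man_a$md5, man_b$md5) # same seed -> identical bytes

  # competition fixture starts at a 1:1 mix
  comp <- readr::read_tsv(file.path(dir_a, "competition.tsv"),
    show_col_types = FALSE
  )
  expect_equal(unique(comp$fraction_true[comp$timepoint == 0]), 0.5)

  # every written trace is readable and carries the expected SNP
  for (f in traces) {
    tr <- read_trace(file.path(dir_a, f))
    loc <- read_snp_locus(file.path(dir_a, "locus.tsv"))
    expect_identical(locate_snp_peak(tr, loc), 9L)
  }

  # chip fixtures cover the three persistence regimes
  expect_setequal(
    man_a$file[man_a$kind == "chip_timecourse"],
    c("chip_passive.tsv", "chip_maintained.tsv", "chip_active_removal.tsv")
  )
  expect_true(file.exists(file.path(dir_a, "manifest.tsv")))
})
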