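test_that("locate_snp_peak finds a unique wildcard-context match", {
  # TTGGA?CCATT with flanks TTGGA/CCATT -> 0-based index 5
  tr <- simulate_trace("TTGGAACCATT", 5, 1.0)
  loc <- snp_locus("A", "C", "TTGGA", "CCATT")
  expect_identical(locate_snp_peak(tr, loc), 5L)

  # generator-recorded ground truth at basecall 9 of the quant fixture
  tr2 <- make_quant_trace(0.3, noise_sd = 0.05, seed = 4)
  expect_identical(
    locate_snp_peak(tr2, quant_locus),
    attr(tr2, "ground_truth")$snp_index
  )

  expect_error(
    locate_snp_peak(tr2, snp_locus("A", "C", "AAAAA", "GGGGG")),
    "locus not found",
    class = "epimem_locus_error"
  )
  # two candidate positions -> ambiguous
  tr3 <- simulate_trace("GGACGGGACG", 2, 1.0)
  expect_error(
    locate_snp_peak(tr3, snp_locus("A", "C", "GG", "CG")),
    "ambiguous",
    class = "epimem_locus_error"
  )
})

test_that("allele quantification handles single-allele and symmetric samples", {
  loc <- quant_locus
  # only the primary allele present -> fraction 1
  pure <- make_quant_trace(1.0)
  expect_equal(quantify_allele_fraction(pure, loc)$fraction_primary, 1.0)
  # identical allele channels in the window -> exactly 0.5
  even <- make_quant_trace(0.5)
  expect_equal(quantify_allele_fraction(even, loc)$fraction_primary, 0.5)
  # all-zero window -> degenerate-signal error
  zero <- make_quant_trace(0.5)
  zero$intensities$A <- 0
  zero$intensities$C <- 0
  expect_error(
    quantify_allele_fraction(zero, loc),
    "degenerate",
    class = "epimem_signal_error"
  )
})

test_that("quantified fraction matches direct integration of the generating Gaussians", {
  for (f in c(0.25, 0.5, 0.75, 0.9)) {
    tr <- make_quant_trace(f)
    gt <- attr(tr, "ground_truth")
    q <- quantify_allele_fraction(tr, quant_locus)
    # oracle: integrate the generating Gaussian components over the same
    # inter-peak-midpoint window
    lo <- gt$center - gt$spacing / 2
    hi <- gt$center + gt$spacing / 2
    a_p <- gauss_area(gt$amp_primary, gt$center, gt$peak_width, lo, hi)
    a_s <- gauss_area(gt$amp_secondary, gt$center, gt$peak_width, lo, hi)
    oracle <- a_p / (a_p + a_s)
    expect_equal(q$fraction_primary, oracle, tolerance = 0.01)
    expect_equal(q$fraction_primary, f, tolerance = 0.01)
  }
})

test_that("fraction is equivariant under channel swap and invariant to scaling", {
  swapped_locus <- snp_locus(
    quant_locus$allele_secondary, quant_locus$allele_primary,
    quant_locus$flank_left, quant_locus$flank_right
  )
  for (seed in 1:5) {
    f <- runif(1, 0.1, 0.9)
    tr <- make_quant_trace(f, noise_sd = 0.05, seed = seed)
    q <- quantify_allele_fraction(tr, quant_locus)$fraction_primary
    q_swap <- quantify_allele_fraction(tr, swapped_locus)$fraction_primary
    expect_equal(q + q_swap, 1.0)

    scaled <- tr
    for (ch in c("A", "C", "G", "T")) {
      scaled$intensities[[ch]] <- scaled$intensities[[ch]] * 3.7
    }
    expect_equal(
      quantify_allele_fraction(scaled, quant_locus)$fraction_primary, q
    )
  }
})

test_that("standard curve recovers exact linear relationships", {
  d <- design_fractions
  identity_curve <- fit_standard_curve(
    tibble::tibble(true_fraction = d, measured_fraction = d)
  )
  expect_equal(identity_curve$slope, 1)
  expect_equal(identity_curve$intercept, 0)
  expect_equal(identity_curve$r_squared, 1)

  # closed-form OLS on an exact affine line
  shifted <- fit_standard_curve(
    tibble::tibble(true_fraction = d, measured_fraction = 0.9 * d + 0.05)
  )
  expect_equal(shifted$slope, 0.9)
  expect_equal(shifted$intercept, 0.05)

  expect_error(
    fit_standard_curve(
      tibble::tibble(true_fraction = c(0.5, 0.5), measured_fraction = c(0, 1))
    ),
    "rank deficient",
    class = "epimem_curve_error"
  )
})

test_that("calibration inverts the curve and reports clamping", {
  d <- design_fractions
  curve <- fit_standard_curve(
    tibble::tibble(true_fraction = d, measured_fraction = 0.9 * d + 0.05)
  )
  cal <- calibrate_fraction(curve, 0.5)
  expect_equal(cal$calibrated, 0.5) # (0.5 - 0.05) / 0.9
  expect_false(cal$clamped)

  identity_curve <- fit_standard_curve(
    tibble::tibble(true_fraction = d, measured_fraction = d)
  )
  expect_equal(calibrate_fraction(identity_curve, 0.37)$calibrated, 0.37)

  offset <- fit_standard_curve(
    tibble::tibble(true_fraction = d, measured_fraction = d + 0.2)
  )
  low <- calibrate_fraction(offset, 0.1)
  expect_equal(low$calibrated, 0)
  expect_true(low$clamped)

  flat <- curve
  flat$slope <- -0.1
  expect_error(calibrate_fraction(flat, 0.5), "slope",
    class = "epimem_curve_error"
  )
})

test_that("tidy/glance expose the standard-curve fit", {
  d <- design_fractions
  curve <- fit_standard_curve(
    tibble::tibble(true_fraction = d, measured_fraction = 0.95 * d + 0.01)
  )
  td <- tidy(curve)
  expect_equal(td$term, c("intercept", "slope"))
  expect_equal(td$estimate, c(0.01, 0.95))
  gl <- glance(curve)
  expect_equal(gl$n, 9L)
  expect_gt(gl$r_squared, 0.999)
})
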