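test_that("mark_fraction reproduces the replication-dilution limits", {
  dil <- mark_decay_params(1, 0, doubling_time = 120)
  expect_equal(mark_fraction(dil, 120), 0.5) # half-life = doubling time
  expect_equal(half_life(dil), 120)

  perfect <- mark_decay_params(1, 0, 120, maintenance_prob = 1)
  expect_equal(mark_fraction(perfect, c(0, 300, 5000)), c(1, 1, 1))
  expect_equal(half_life(perfect), Inf)

  half_kept <- mark_decay_params(1, 0, 120, maintenance_prob = 0.5)
  expect_equal(mark_fraction(half_kept, 240), 0.75^2) # 0.5625
})

test_that("expected_signal is background + s0 * mark fraction", {
  p <- mark_decay_params(10, 0, 120)
  expect_equal(expected_signal(p, 480), 0.625) # 10 * 2^-4
  for (m in c(0, 0.5, 1)) {
    for (k in c(0, 0.01)) {
      q <- mark_decay_params(7, 2, 120, m, k)
      expect_equal(expected_signal(q, 0), 9)
    }
  }
  flat <- mark_decay_params(10, 2, 120, maintenance_prob = 1)
  expect_equal(expected_signal(flat, 600), 12)
})

test_that("expected_signal decreases in t and half-life increases in m", {
  tt <- seq(0, 600, by = 25)
  for (m in c(0, 0.3, 0.8)) {
    p <- mark_decay_params(5, 1, 120, maintenance_prob = m)
    expect_true(all(diff(expected_signal(p, tt)) < 0))
  }
  hls <- vapply(
    seq(0, 0.9, by = 0.1),
    function(m) half_life(mark_decay_params(1, 0, 120, m)), 0
  )
  expect_true(all(diff(hls) > 0))
})

test_that("division simulator matches the closed form ((1+m)/2)^g", {
  # m = 1: nothing is ever lost
  perfect <- simulate_locus_divisions(
    mark_decay_params(1, 0, 120, maintenance_prob = 1), 500, 5,
    seed = 1
  )
  expect_equal(perfect$fraction, rep(1, 6))

  # m = 0, one division of 1e4 nucleosomes: binomial around 0.5
  one_div <- simulate_locus_divisions(
    mark_decay_params(1, 0, 120), 1e4, 1,
    seed = 2
  )
  expect_equal(one_div$fraction[2], 0.5, tolerance = 0.015 / 0.5)

  # m = 0.5, mean over 1000 runs at division 2 -> 0.75^2
  means <- vapply(seq_len(1000), function(i) {
    simulate_locus_divisions(
      mark_decay_params(1, 0, 120, maintenance_prob = 0.5), 100, 2,
      seed = 100 + i
    )$fraction[3]
  }, 0)
  expect_equal(mean(means), 0.5625, tolerance = 0.01 / 0.5625)

  # trajectory-level agreement across divisions (MC error ~ 3 binomial SE)
  m <- 0.3
  traj <- vapply(seq_len(400), function(i) {
    simulate_locus_divisions(
      mark_decay_params(1, 0, 120, maintenance_prob = m), 200, 4,
      seed = 2000 + i
    )$fraction
  }, numeric(5))
  expected <- ((1 + m) / 2)^(0:4)
  mc_se <- sqrt(expected * (1 - expected) / (200 * 400))
  expect_true(all(abs(rowMeans(traj) - expected) <= 3 * mc_se + 1e-12))
})

test_that("noise-free dilution data fit back to half-life = doubling time", {
  truth <- mark_decay_params(10, 1, 120)
  tc <- simulate_chip_timecourse(truth, seq(0, 480, 96), noise_sd = 0)
  fit <- fit_decay(tc, 120, "maintenance")
  expect_lte(fit$params$maintenance_prob, 0.02)
  expect_equal(fit$half_life, 120, tolerance = 0.01)
  expect_equal(fit$params$s0, 10, tolerance = 1e-4)
  expect_equal(fit$params$background, 1, tolerance = 1e-4)
})

test_that("flat data fit to near-perfect maintenance", {
  tc <- tibble::tibble(time = seq(0, 480, 96), signal = rep(12, 6))
  fit <- fit_decay(tc, 120, "maintenance")
  expect_gte(fit$params$maintenance_prob, 0.98)
})

test_that("an active-removal rate is recovered within 10% without noise", {
  truth <- mark_decay_params(10, 1, 120, removal_rate = 0.05)
  tc <- simulate_chip_timecourse(truth, seq(0, 480, 96), noise_sd = 0)
  fit <- fit_decay(tc, 120, "maintenance_plus_removal")
  expect_equal(fit$params$removal_rate, 0.05, tolerance = 0.10)
  expect_equal(fit$params$maintenance_prob, 0)
})

test_that("underdetermined fits raise an identifiability error", {
  tc <- tibble::tibble(time = c(0, 100, 200), signal = c(10, 6, 4))
  expect_error(
    fit_decay(tc, 120, "maintenance_plus_removal"),
    "identifiable",
    class = "epimem_identifiability_error"
  )
  # anchoring the background frees one parameter
  expect_s3_class(
    fit_decay(tc, 120, "maintenance_plus_removal", background = 1),
    "mark_decay_fit"
  )
})

test_that("persistence in generations follows the detection rule", {
  # flat signal above threshold through 480 min at T_d 120 -> 4 generations
  flat <- tibble::tibble(time = seq(0, 480, 120), signal = rep(5, 5))
  expect_equal(
    persistence_generations(flat, 120, background = 1)$generations, 4
  )

  # 8x threshold at t = 0, halving each generation -> detectable through g = 3
  dil <- tibble::tibble(
    time = seq(0, 480, 120),
    signal = 8 * 2^(-seq(0, 480, 120) / 120)
  )
  res <- persistence_generations(dil, 120, background = 0, threshold = 1)
  expect_equal(res$generations, 3)
  expect_equal(res$t_star_min, 360)

  # never above threshold -> zero persistence, not an error
  low <- tibble::tibble(time = seq(0, 480, 120), signal = rep(0.5, 5))
  expect_equal(
    persistence_generations(low, 120, background = 1)$generations, 0
  )

  # background defaults to the control-locus mean
  with_ctrl <- tibble::tibble(
    time = seq(0, 480, 120), signal = rep(5, 5), control = rep(1, 5)
  )
  expect_equal(
    persistence_generations(with_ctrl, 120)$generations, 4
  )
})

test_that("single noisy time courses classify into the generating regime", {
  regimes <- list(
    passive_dilution = mark_decay_params(10, 1, 120),
    heritable = mark_decay_params(10, 1, 120, maintenance_prob = 0.95),
    active_removal = mark_decay_params(10, 1, 120, removal_rate = 0.03)
  )
  for (nm in names(regimes)) {
    tc <- simulate_chip_timecourse(
      regimes[[nm]], seq(0, 480, 96),
      noise_sd = 0.05, seed = 42 + match(nm, names(regimes))
    )
    rep <- classify_heritability(tc, 120)
    expect_identical(rep$classification, nm)
    expect_equal(nrow(tidy(rep)), 3L)
    expect_identical(glance(rep)$classification, nm)
  }
})

test_that("classification is deterministic given the same time course", {
  tc <- simulate_chip_timecourse(
    mark_decay_params(10, 1, 120, maintenance_prob = 0.9),
    seq(0, 480, 96),
    noise_sd = 0.05, seed = 99
  )
  a <- classify_heritability(tc, 120)
  b <- classify_heritability(tc, 120)
  expect_identical(glance(a), glance(b))
})
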