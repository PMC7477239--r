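test_that("onset detection follows the consecutive-run rule", {
  expect_identical(detect_onset(c(15, 18, 21, 22, 23)), 3L)
  expect_identical(detect_onset(c(21, 19, 22, 23, 21)), 3L)
  expect_identical(detect_onset(c(15, 18, 19, 20, 20)), NA_integer_)
  expect_identical(detect_onset(c(21, 22), run_length = 2), 1L)
  expect_identical(detect_onset(c(21, 22), run_length = 3), NA_integer_)
  expect_error(detect_onset(numeric(0)), "empty")
})

test_that("raising the onset threshold never gives an earlier onset", {
  set.seed(123)
  for (i in 1:50) {
    x <- 10 + cumsum(rnorm(30, 0.8, 3))
    onsets <- vapply(c(15, 20, 25, 30), function(th) {
      o <- detect_onset(x, threshold = th)
      if (is.na(o)) length(x) + 1 else as.numeric(o)
    }, numeric(1))
    expect_true(all(diff(onsets) >= 0))
  }
})

test_that("control eye with consensual rise disabled is constant at baseline", {
  p <- cohort_params(tonometry_noise_sd = 0, baseline_iop_sd = 0,
                     consensual = FALSE)
  s <- simulate_iop_series(p, group = 1, treatment = "control", seed = 1)
  expect_equal(s$weekly_iop, rep(s$baseline_iop, p$study_weeks))
  expect_equal(s$baseline_iop, 13)
  expect_length(s$injection_weeks, 0)
})

test_that("noise-free OHT dynamics reproduce a hand-simulated trace", {
  p <- cohort_params(tonometry_noise_sd = 0, iop_fluctuation_frac = 0,
                     baseline_iop_sd = 0, baseline_iop_mean = 12,
                     injection_effect = 8, group1_plateau = 43,
                     dose_half = 22, dose_slope = 3.5, relax_rate = 0.6,
                     reinjection_threshold_g1 = 30)
  s <- simulate_iop_series(p, group = 1, treatment = "OHT", seed = 1)
  # independent hand simulation of the published update rule
  state <- 12; dose <- 0; prev <- 12
  ref <- numeric(p$study_weeks); inj <- integer(0)
  for (w in seq_len(p$study_weeks)) {
    if (prev < 30) { dose <- dose + 8; inj <- c(inj, w) }
    target <- 12 + (43 - 12) / (1 + exp(-(dose - 22) / 3.5))
    state <- state + 0.6 * (target - state)
    ref[w] <- state
    prev <- state
  }
  expect_equal(s$weekly_iop, ref, tolerance = 1e-12)
  expect_identical(s$injection_weeks, inj)
  expect_identical(s$onset_week, detect_onset(ref))
})

test_that("series are reproducible and respect basic invariants", {
  p <- cohort_params()
  a <- simulate_iop_series(p, 1, "OHT", seed = 77)
  b <- simulate_iop_series(p, 1, "OHT", seed = 77)
  expect_identical(a, b)
  expect_true(all(a$weekly_iop > 0))
  expect_true(all(a$injection_weeks %in% seq_along(a$weekly_iop)))
  if (!is.na(a$onset_week)) {
    run <- a$weekly_iop[a$onset_week:(a$onset_week + p$onset_run_length - 1)]
    expect_true(all(run > p$onset_threshold))
  }
})

test_that("Group-1 induction calibration: ~6 injections, onset ~week 5", {
  p <- cohort_params()
  inj <- onset <- numeric(100)
  for (i in 1:100) {
    s <- simulate_iop_series(p, 1, "OHT", seed = i)
    onset[i] <- ifelse(is.na(s$onset_week), NA, s$onset_week)
    horizon <- ifelse(is.na(s$onset_week), p$study_weeks,
                      s$onset_week + p$onset_run_length - 1)
    inj[i] <- sum(s$injection_weeks <= horizon)
  }
  expect_true(mean(inj) >= 4 && mean(inj) <= 8)
  expect_true(mean(onset, na.rm = TRUE) >= 3 && mean(onset, na.rm = TRUE) <= 7)
  expect_lt(mean(is.na(onset)), 0.05)
})

test_that("Group-1 OHT period mean IOP falls in the study's calibration band", {
  p <- cohort_params()
  pm <- vapply(1:100, function(i) {
    s <- simulate_iop_series(p, 1, "OHT", seed = i)
    oht_period_summary(monthly_aggregate(s))$mean
  }, numeric(1))
  expect_gt(mean(pm), 43 - 2 * 6.3)
  expect_lt(mean(pm), 43 + 2 * 6.3)
})
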