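test_that("two equally weighted segments reproduce the exact two-point line", {
  # HR 120 -> VO2 21, HR 150 -> VO2 28; slope 7/30, value at 190 = 37.33 -> 37
  segs <- make_segments(c(120, 150), c(21, 28))
  p <- make_profile(age = 30, hr_max = 190)
  est <- estimate_vo2max(segs, p, hr_max = 190)
  expect_equal(est$slope, 7 / 30)
  expect_equal(est$intercept, 21 - 120 * 7 / 30)
  expect_equal(est$vo2max, 37)
  expect_equal(est$quality, "low_segments")  # below the 3-segment minimum
})

test_that("segments at a single heart-rate level give no reliable data", {
  segs <- make_segments(c(140, 140, 140), c(24, 25, 26))
  est <- estimate_vo2max(segs, make_profile())
  expect_equal(est$quality, "no_reliable_data")
  expect_true(is.na(est$vo2max))
})

test_that("rounding of the extrapolated value is half-up", {
  expect_equal(round_half_up(c(36.5, 37.5, 36.49)), c(37, 38, 36))
  segs <- make_segments(c(100, 200), c(10, 35))
  # line value at hr_max 190 = 10 + 25 * 90/100 = 32.5 -> 33
  est <- estimate_vo2max(segs, make_profile(), hr_max = 190)
  expect_equal(est$vo2max, 33)
})

test_that("the pipeline recovers ground truth from clean ramps", {
  p <- make_profile(true_vo2max = 35)
  ses <- simulate_run_session(p, scenario_clean_ramp(), seed = 7)
  fit <- swt_vo2max(ses)
  expect_equal(fit$quality, "ok")
  expect_lte(abs(fit$vo2max - 35), 2)
  # noise-free run: within 1 of the truth
  ses0 <- simulate_run_session(p, scenario_clean_ramp(), seed = 7,
                               hr_noise_sd = 0, speed_noise_sd = 0)
  fit0 <- swt_vo2max(ses0)
  expect_lte(abs(fit0$vo2max - 35), 1)
})

test_that("the pipeline is deterministic and artifact-robust", {
  p <- make_profile(true_vo2max = 42)
  ses <- simulate_run_session(p, scenario_with_artifacts(), seed = 11)
  f1 <- swt_vo2max(ses)
  f2 <- swt_vo2max(ses)
  expect_identical(f1$vo2max, f2$vo2max)
  expect_identical(f1$segments, f2$segments)
  # embedded stop/downhill/sprint barely move the estimate
  clean <- simulate_run_session(p, scenario_clean_ramp(to = 0.80), seed = 11)
  fc <- swt_vo2max(clean)
  expect_setequal(unique(f1$excluded_spans$reason),
                  c("downhill_pattern", "hr_rise_at_zero_speed",
                    "short_high_intensity"))
  expect_lte(abs(f1$vo2max - fc$vo2max), 1)
})

test_that("fit methods expose coefficients, predictions and residuals", {
  p <- make_profile(true_vo2max = 35)
  ses <- simulate_run_session(p, scenario_clean_ramp(), seed = 3)
  fit <- swt_vo2max(ses)
  cf <- coef(fit)
  expect_named(cf, c("intercept", "slope"))
  expect_equal(unname(predict(fit, hr = 0)), unname(cf["intercept"]))
  expect_equal(unname(predict(fit)), unname(cf["intercept"] +
                                              cf["slope"] * fit$hr_max))
  expect_equal(length(residuals(fit)), nrow(fit$segments))
  expect_output(print(fit), "VO2max estimate")
  expect_output(summary(fit), "Reliable segments")
})
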