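test_that("session constructor validates its inputs", {
  p <- make_profile()
  expect_error(run_session(0:9, rep(100, 10), rep(-1, 10), p), "nonnegative")
  expect_error(run_session(c(0, 1, 1, 2), rep(100, 4), rep(5, 4), p),
               "strictly increasing")
  expect_error(run_session(c(0, 1, 3, 6), rep(100, 4), rep(5, 4), p),
               "uniform")
  expect_error(run_session(0:3, c(100, 100, 100), rep(5, 4), p),
               "equal lengths")
  expect_error(run_session(0:3, c(100, 250, 100, 100), rep(5, 4), p),
               "\\[30, 230\\]")
})

test_that("same profile + scenario + seed reproduce the session exactly", {
  p <- make_profile()
  a <- simulate_run_session(p, scenario_clean_ramp(), seed = 42)
  b <- simulate_run_session(p, scenario_clean_ramp(), seed = 42)
  expect_identical(a$hr_bpm, b$hr_bpm)
  expect_identical(a$speed_kmh, b$speed_kmh)
  c <- simulate_run_session(p, scenario_clean_ramp(), seed = 43)
  expect_false(identical(a$hr_bpm, c$hr_bpm))
})

test_that("noise-free steady phases converge to the linear HR-speed relation", {
  p <- make_profile(true_vo2max = 40)
  sc <- swt_scenario(phase_steady(300, 0.6), phase_steady(300, 0.75))
  ses <- simulate_run_session(p, sc, seed = 1, hr_noise_sd = 0,
                              speed_noise_sd = 0)
  # after ~5 time constants the lag transient is gone; residuals ~ 0
  for (burn in c(300)) {
    idx <- (burn - 50):burn
    expected <- p$hr_rest + (p$hr_max - p$hr_rest) *
      3.5 * ses$speed_kmh[idx] / p$true_vo2max
    expect_lt(max(abs(ses$hr_bpm[idx] - expected)), 0.5)
  }
  idx2 <- 550:600
  expected2 <- p$hr_rest + (p$hr_max - p$hr_rest) *
    3.5 * ses$speed_kmh[idx2] / p$true_vo2max
  expect_lt(max(abs(ses$hr_bpm[idx2] - expected2)), 0.5)
})

test_that("artifact phases break the HR-speed coupling as named", {
  p <- make_profile()
  ses <- simulate_run_session(p, scenario_with_artifacts(), seed = 7,
                              hr_noise_sd = 0, speed_noise_sd = 0)
  sc <- attr(ses, "scenario")
  ends <- cumsum(sc$duration_s)
  starts <- ends - sc$duration_s + 1
  stop_idx <- starts[sc$phase == "stop_hr_rise"]:ends[sc$phase == "stop_hr_rise"]
  expect_true(all(ses$speed_kmh[stop_idx] == 0))
  expect_gt(ses$hr_bpm[max(stop_idx)], ses$hr_bpm[min(stop_idx)] + 10)
  dh_idx <- starts[sc$phase == "downhill"]:ends[sc$phase == "downhill"]
  expect_true(all(ses$speed_kmh[dh_idx] >= 6))
  expect_lt(ses$hr_bpm[max(dh_idx)], ses$hr_bpm[min(dh_idx)] - 10)
})

test_that("an all-stop scenario yields no reliable data downstream", {
  p <- make_profile()
  ses <- simulate_run_session(p, scenario_all_stop(300), seed = 2)
  fit <- swt_vo2max(ses)
  expect_equal(fit$quality, "no_reliable_data")
  expect_true(is.na(fit$vo2max))
})
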