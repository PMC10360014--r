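test_that("theoretical VO2 is 3.5 x speed and scales exactly", {
  expect_equal(theoretical_vo2(10), 35)
  expect_equal(theoretical_vo2(0), 0)
  expect_equal(theoretical_vo2(8.4), 29.4)
  expect_error(theoretical_vo2(-1), "nonnegative")
  sp <- c(0, 3.2, 7.77, 12)
  expect_equal(theoretical_vo2(3 * sp), 3 * theoretical_vo2(sp))
})

test_that("a steady 120 s block at 65% HRmax yields exactly one segment", {
  p <- make_profile()                 # hr_max = 185
  hr <- rep(0.65 * 185, 120)          # 120.25 bpm, zone [60, 70)
  ses <- run_session(0:119, hr, rep(6.5, 120), p)
  segs <- segment_by_zone(ses, rep(TRUE, 120))
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$zone, 2L)
  expect_equal(segs$duration, 120)
  expect_equal(segs$mean_hr, 0.65 * 185)
  expect_equal(segs$theoretical_vo2, 3.5 * 6.5)
})

test_that("blocks shorter than 20 s and unmasked samples produce nothing", {
  p <- make_profile()
  ses <- run_session(0:9, rep(130, 10), rep(7, 10), p)
  expect_equal(nrow(segment_by_zone(ses, rep(TRUE, 10))), 0L)
  ses2 <- run_session(0:119, rep(130, 120), rep(7, 120), p)
  expect_equal(nrow(segment_by_zone(ses2, rep(FALSE, 120))), 0L)
})

test_that("long runs split at the 600 s cap and at the drift threshold", {
  p <- make_profile()
  ses <- run_session(0:699, rep(130, 700), rep(7, 700), p)
  segs <- segment_by_zone(ses, rep(TRUE, 700))
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$duration, c(600, 100))
  # 10 bpm of drift within one zone must split (threshold 5 bpm)
  hr <- seq(113, 123, length.out = 300)
  ses2 <- run_session(0:299, hr, rep(7, 300), p)
  segs2 <- segment_by_zone(ses2, rep(TRUE, 300))
  expect_gte(nrow(segs2), 2L)
  expect_true(all(segs2$hr_drift <= 5 + 1e-9))
})

test_that("samples below 50% HRmax are never segmented", {
  p <- make_profile()
  ses <- run_session(0:119, rep(85, 120), rep(5, 120), p)  # 46% HRmax
  expect_equal(nrow(segment_by_zone(ses, rep(TRUE, 120))), 0L)
})

test_that("segment weights follow the duration/zone rule and sum to one", {
  segs <- make_segments(c(120, 150), c(21, 28), duration = c(60, 60))
  w <- weight_segments(segs)$weight
  expect_equal(w, c(0.5, 0.5))
  expect_equal(sum(w), 1, tolerance = 1e-12)

  # equal durations, same zone: preferred-window vs not gives 2:1 raw weights
  segs2 <- make_segments(c(120, 150), c(21, 28), duration = c(60, 500))
  w2 <- weight_segments(segs2)$weight
  expect_equal(w2[1] / w2[2], (60 * 1) / (500 * 0.5))
  # equal preferred durations, zones 1 vs 3: zone factors 1 vs 1.5
  segs3 <- make_segments(c(120, 150), c(21, 28), duration = c(60, 60))
  segs3$zone <- c(1, 3)
  w3 <- weight_segments(segs3)$weight
  expect_equal(w3[2] / w3[1], 1.5)

  expect_error(weight_segments(make_segments(numeric(0), numeric(0))),
               "empty")
})
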