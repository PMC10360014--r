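# Shared fixture builders (all synthetic, generated at test time).

make_profile <- function(id = "p1", age = 35, sex = "female", height = 165,
                         weight = 60, hr_rest = 68, hr_max = NULL,
                         true_vo2max = 35) {
  participant_profile(id, age = age, sex = sex, height = height,
                      weight = weight, hr_rest = hr_rest, hr_max = hr_max,
                      true_vo2max = true_vo2max)
}

# minimal segment table for direct estimator tests
make_segments <- function(mean_hr, theoretical_vo2, duration = 60,
                          zone = 3, weight = NA_real_) {
  k <- length(mean_hr)
  data.frame(start = seq(1, by = 100, length.out = k),
             end = seq(60, by = 100, length.out = k),
             duration = rep_len(duration, k), mean_hr = mean_hr,
             hr_drift = rep_len(2, k),
             mean_speed = theoretical_vo2 / 3.5, zone = rep_len(zone, k),
             theoretical_vo2 = theoretical_vo2,
             weight = rep_len(weight, k))
}

# steady-block session bypassing the simulator: HR and speed gently rising
# so the activity mask is all-true after the first sample
make_ramp_session <- function(n = 300, hr0 = 120, hr_slope = 0.05,
                              speed0 = 7, speed_slope = 0.002,
                              profile = make_profile()) {
  t <- 0:(n - 1)
  run_session(t, hr0 + hr_slope * t, speed0 + speed_slope * t, profile)
}
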