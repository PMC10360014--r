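test_that("constant error is the sample mean/SD of the differences", {
  expect_equal(constant_error(c(1, 2, 3), c(1, 2, 3)),
               c(mean = 0, sd = 0))
  ref <- c(10, 20, 30, 40)
  est <- ref + c(1, 1, 1, 3)
  expect_equal(constant_error(est, ref), c(mean = 1.5, sd = 1))
  expect_error(constant_error(1, 1), "at least 2")
})

test_that("paired t equals the one-sample t of the differences", {
  set.seed(21)
  ref <- rnorm(25, 30, 5)
  est <- ref + rnorm(25, 1, 2)
  got <- paired_t(est, ref)
  oracle <- t.test(est, ref, paired = TRUE)
  expect_equal(got$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(got$df, unname(oracle$parameter))
  expect_equal(got$p, oracle$p.value, tolerance = 1e-12)
  # zero-variance differences are flagged degenerate
  deg <- paired_t(c(12, 22, 32), c(10, 20, 30))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$t))
})

test_that("Pearson r and r^2 match the covariance formula", {
  set.seed(22)
  ref <- rnorm(20, 30, 5)
  est <- 0.8 * ref + rnorm(20, 0, 2)
  got <- pearson_r2(est, ref)
  r_oracle <- sum((est - mean(est)) * (ref - mean(ref))) /
    sqrt(sum((est - mean(est))^2) * sum((ref - mean(ref))^2))
  expect_equal(unname(got["r"]), r_oracle, tolerance = 1e-12)
  expect_equal(unname(got["r_squared"]), r_oracle^2, tolerance = 1e-12)
  expect_equal(unname(pearson_r2(2 * ref, ref)["r"]), 1)
  expect_equal(unname(pearson_r2(-ref, ref)["r"]), -1)
  expect_error(pearson_r2(rep(1, 5), 1:5), "zero-variance")
})

test_that("ICC forms match the two-way ANOVA mean-squares oracle", {
  set.seed(23)
  ref <- rnorm(15, 30, 5)
  est <- ref + rnorm(15, 1, 2)
  got <- icc_pair(est, ref)
  # independent oracle: mean squares from aov on the long layout
  d <- data.frame(y = c(est, ref),
                  subj = factor(rep(1:15, 2)),
                  method = factor(rep(c("e", "r"), each = 15)))
  ms <- summary(aov(y ~ subj + method, data = d))[[1]]$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc_c <- (msr - mse) / (msr + mse)
  icc_a <- (msr - mse) / (msr + mse + 2 * (msc - mse) / 15)
  expect_equal(unname(got["consistency"]), icc_c, tolerance = 1e-10)
  expect_equal(unname(got["absolute_agreement"]), icc_a, tolerance = 1e-10)
})

test_that("ICC and r respond to fixed offsets as theory dictates", {
  set.seed(24)
  ref <- rnorm(20, 30, 5)
  est <- ref + rnorm(20, 0, 1)
  base <- icc_pair(est, ref)
  shifted_both <- icc_pair(est + 7, ref + 7)
  expect_equal(base, shifted_both, tolerance = 1e-10)
  expect_equal(pearson_r2(est + 7, ref + 7), pearson_r2(est, ref),
               tolerance = 1e-10)
  one_shifted <- icc_pair(est + 7, ref)
  expect_lt(unname(one_shifted["absolute_agreement"]),
            unname(one_shifted["consistency"]))
  expect_lt(unname(one_shifted["absolute_agreement"]),
            unname(base["absolute_agreement"]))
  # identical series: both forms 1
  ident <- icc_pair(ref, ref)
  expect_equal(unname(ident), c(1, 1))
})

test_that("MAE/MAPE match hand arithmetic and MAPE is scale-invariant", {
  got <- mae_mape(c(33, 27), c(30, 30))
  expect_equal(unname(got), c(3, 10))
  expect_equal(unname(mae_mape(c(30, 30), c(30, 30))), c(0, 0))
  set.seed(25)
  ref <- runif(30, 20, 50)
  est <- ref + rnorm(30)
  expect_equal(unname(mae_mape(3 * est, 3 * ref)["mape_pct"]),
               unname(mae_mape(est, ref)["mape_pct"]), tolerance = 1e-12)
  expect_error(mae_mape(c(1, 2), c(0, 2)), "positive")
})

test_that("Bland-Altman limits use bias +/- 1.96 SD", {
  set.seed(26)
  ref <- rnorm(40, 30, 5)
  est <- ref + rnorm(40, 1, 2)
  ce <- constant_error(est, ref)
  ba <- bland_altman(est, ref)
  expect_equal(ba$bias, unname(ce["mean"]))
  expect_equal(ba$loa_width, unname(3.92 * ce["sd"]), tolerance = 1e-12)
  expect_equal(ba$loa_upper - ba$loa_lower, ba$loa_width)
  z <- bland_altman(ref, ref)
  expect_equal(z$bias, 0)
  expect_equal(z$loa_width, 0)
  # bias flips sign when the methods are exchanged
  expect_equal(bland_altman(ref, est)$bias, -ba$bias)
})

test_that("the aggregate report is internally consistent", {
  coh <- simulate_cohort(cohort_config(n_participants = 120, seed = 6))
  rep <- vo2_agreement(coh$vo2max_swt, coh$vo2max_cpet)
  expect_equal(rep$bias, rep$ce_mean)
  expect_equal(rep$r_squared, rep$pearson_r^2)
  expect_equal(rep$loa_width, 2 * 1.96 * rep$ce_sd)
  expect_output(print(rep), "Bland-Altman")
})
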