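# Brute-force O(n^2) concordance oracle: pairs (case, control), ties 1/2.
auc_bruteforce <- function(score, label) {
  x <- score[as.logical(label)]
  y <- score[!as.logical(label)]
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

test_that("perfectly separated scores give AUC 1 and a perfect cutoff", {
  score <- c(1, 2, 3, 10, 11, 12)
  label <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  roc <- roc_curve(score, label)
  expect_equal(roc$auc, 1)
  op <- youden_optimal(roc)
  expect_equal(op$youden_j, 1)
  expect_equal(op$sensitivity, 100)
  expect_equal(op$specificity, 100)
  expect_true(op$cutoff > 3 && op$cutoff < 10)
  # fully reversed labels under the same direction give AUC 0
  expect_equal(roc_curve(score, !label)$auc, 0)
})

test_that("AUC equals the brute-force pairwise concordance with ties", {
  set.seed(51)
  for (i in 1:5) {
    n <- 120
    label <- rbinom(n, 1, 0.4) == 1
    score <- round(rnorm(n, mean = label), 1)  # rounding forces ties
    roc <- roc_curve(score, label)
    expect_equal(roc$auc, auc_bruteforce(score, label), tolerance = 1e-12)
    # lower_risk direction is the complement relation
    roc_l <- roc_curve(score, label, direction = "lower_risk")
    expect_equal(roc_l$auc, auc_bruteforce(-score, label), tolerance = 1e-12)
  }
})

test_that("the ROC curve is invariant to monotone score transforms", {
  set.seed(52)
  label <- rbinom(80, 1, 0.5) == 1
  score <- rnorm(80, mean = 0.8 * label)
  r1 <- roc_curve(score, label)
  r2 <- roc_curve(exp(score), label)
  expect_equal(r1$auc, r2$auc, tolerance = 1e-12)
  expect_equal(r1$auc_se, r2$auc_se, tolerance = 1e-12)
  expect_equal(r1$curve$sensitivity, r2$curve$sensitivity)
  expect_equal(r1$curve$specificity, r2$curve$specificity)
})

test_that("single-class labels and incomplete inputs are rejected", {
  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both outcome classes")
  expect_error(roc_curve(c(1, NA, 3), c(TRUE, FALSE, TRUE)), "complete")
})

test_that("the Youden point matches an exhaustive threshold scan", {
  set.seed(53)
  label <- rbinom(150, 1, 0.35) == 1
  score <- round(rnorm(150, mean = label), 1)
  roc <- roc_curve(score, label)
  op <- youden_optimal(roc)
  # oracle: scan rule "positive iff score >= t" over all candidate thresholds
  cand <- c(-Inf, sort(unique(score)), Inf)
  j_or <- vapply(cand, function(t) {
    sens <- mean(score[label] >= t)
    spec <- mean(score[!label] < t)
    sens + spec - 1
  }, numeric(1))
  expect_equal(op$youden_j, max(j_or), tolerance = 1e-12)
  # predictive values agree with the confusion table at the cutoff
  cf <- op$confusion
  expect_equal(op$ppv, 100 * cf["tp"] / (cf["tp"] + cf["fp"]),
               ignore_attr = TRUE)
  expect_equal(op$npv, 100 * cf["tn"] / (cf["tn"] + cf["fn"]),
               ignore_attr = TRUE)
  expect_equal(op$sensitivity, 100 * cf["tp"] / (cf["tp"] + cf["fn"]),
               ignore_attr = TRUE)
})

test_that("Youden ties resolve toward the higher-specificity cutoff", {
  # two cutoffs reach J = 0.5: calling {5,9,10} positive (sens 1, spec .5)
  # and calling {10} positive (sens .5, spec 1); the rule picks the latter.
  score <- c(1, 5, 9, 10)
  label <- c(FALSE, TRUE, FALSE, TRUE)
  op <- youden_optimal(roc_curve(score, label))
  expect_equal(op$specificity, 100)
  expect_gt(op$cutoff, 9)
})

test_that("DeLong comparison matches the independent pROC implementation", {
  skip_if_not_installed("pROC")
  coh <- simulate_cohort(cohort_config(n_participants = 300, seed = 17))
  roc <- roc_curve(coh$vo2max_swt, coh$ams, direction = "lower_risk")
  p_roc <- pROC::roc(coh$ams, coh$vo2max_swt, direction = ">",
                     levels = c(FALSE, TRUE), quiet = TRUE)
  expect_equal(roc$auc, as.numeric(pROC::auc(p_roc)), tolerance = 1e-12)
  ci <- pROC::ci.auc(p_roc, method = "delong")
  expect_equal(roc$auc_se, (ci[3] - ci[1]) / (2 * qnorm(0.975)),
               tolerance = 1e-9)
  cmp <- compare_auc_paired(coh$rdw_cv, coh$vo2max_swt, coh$ams,
                            direction1 = "higher_risk",
                            direction2 = "lower_risk")
  # pROC wants both curves in the same direction, so negate the device score
  p_rdw <- pROC::roc(coh$ams, coh$rdw_cv, direction = "<",
                     levels = c(FALSE, TRUE), quiet = TRUE)
  p_neg <- pROC::roc(coh$ams, -coh$vo2max_swt, direction = "<",
                     levels = c(FALSE, TRUE), quiet = TRUE)
  p_test <- pROC::roc.test(p_rdw, p_neg, method = "delong", paired = TRUE)
  expect_equal(unname(cmp$z), unname(p_test$statistic), tolerance = 1e-9)
  expect_equal(cmp$p_two_sided, p_test$p.value, tolerance = 1e-9)
})

test_that("comparing a score with itself gives z = 0 and p = 1", {
  set.seed(54)
  label <- rbinom(60, 1, 0.5) == 1
  score <- rnorm(60, mean = label)
  cmp <- compare_auc_paired(score, score, label)
  expect_equal(cmp$z, 0)
  expect_equal(cmp$p_two_sided, 1)
  # a monotone transform leaves the AUC difference at zero too
  cmp2 <- compare_auc_paired(score, 3 * score + 5, label)
  expect_equal(cmp2$difference, 0)
  expect_equal(cmp2$p_two_sided, 1)
})

test_that("swapping the two scores flips the sign of the statistic", {
  set.seed(55)
  label <- rbinom(100, 1, 0.4) == 1
  s1 <- rnorm(100, mean = 0.9 * label)
  s2 <- rnorm(100, mean = 0.4 * label)
  a <- compare_auc_paired(s1, s2, label)
  b <- compare_auc_paired(s2, s1, label)
  expect_equal(a$difference, -b$difference, tolerance = 1e-12)
  expect_equal(a$z, -b$z, tolerance = 1e-12)
  expect_equal(a$p_two_sided, b$p_two_sided, tolerance = 1e-12)
})

test_that("the combined model score discriminates at least as well", {
  coh <- simulate_cohort(cohort_config(n_participants = 400, seed = 19))
  fit <- fit_logistic(ams ~ vo2max_swt + rdw_cv, coh)
  s <- combined_model_score(fit, coh)
  auc_comb <- roc_curve(s, coh$ams)$auc
  auc_swt <- roc_curve(coh$vo2max_swt, coh$ams, direction = "lower_risk")$auc
  auc_rdw <- roc_curve(coh$rdw_cv, coh$ams)$auc
  # in-sample, the fitted combination cannot do much worse than either input
  expect_gte(auc_comb, max(auc_swt, auc_rdw) - 0.02)
  # a model using one predictor scores equivalently to the raw predictor
  fit1 <- fit_logistic(ams ~ rdw_cv, coh)
  expect_equal(roc_curve(combined_model_score(fit1, coh), coh$ams)$auc,
               auc_rdw, tolerance = 1e-12)
})
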