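# ROC curves, Youden-optimal operating points and the paired DeLong AUC
# comparison. Scores are oriented internally so larger means higher risk;
# direction = "lower_risk" (used for VO2max, where low fitness predicts AMS)
# negates the score, and cutoffs are reported back on the original scale.

orient_scores <- function(score, direction) {
  if (direction == "lower_risk") -score else score
}

# Mann-Whitney AUC with tie correction (ties count 1/2)
auc_mw <- function(s, label) {
  n1 <- sum(label)
  n0 <- sum(!label)
  r <- rank(s, ties.method = "average")
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement values: V10 per case, V01 per control. Midrank
# formulation (O(n log n)); ties count 1/2.
delong_placements <- function(s, label) {
  x <- s[label]
  y <- s[!label]
  n1 <- length(x)
  n0 <- length(y)
  tz <- rank(c(x, y), ties.method = "average")
  tx <- rank(x, ties.method = "average")
  ty <- rank(y, ties.method = "average")
  list(v10 = (tz[seq_len(n1)] - tx) / n0,
       v01 = 1 - (tz[n1 + seq_len(n0)] - ty) / n1)
}

#' ROC curve
#'
#' Builds the full ROC curve over all thresholds midway between adjacent
#' distinct scores (plus infinite sentinels) and computes the AUC as the
#' Mann-Whitney concordance statistic with ties counted 1/2. The AUC
#' standard error comes from the DeLong placement-value decomposition.
#'
#' @param score numeric risk score.
#' @param label binary outcome (logical or 0/1); both classes must occur.
#' @param direction `"higher_risk"` if larger scores indicate the outcome,
#'   `"lower_risk"` if smaller scores do (e.g. VO2max for AMS).
#' @return an object of class `roc_curve`: `curve` (a `data.frame` with
#'   `cutoff`, `sensitivity`, `specificity` on the original score scale),
#'   `auc`, `auc_se`, `direction`, `n_pos`, `n_neg`; the oriented scores and
#'   labels are kept for downstream operating-point calculations.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_participants = 100, seed = 5))
#' roc_curve(coh$vo2max_swt, coh$ams, direction = "lower_risk")
#' @export
roc_curve <- function(score, label,
                      direction = c("higher_risk", "lower_risk")) {
  direction <- match.arg(direction)
  label <- as.logical(label)
  stopifnot(is.numeric(score), length(score) == length(label))
  if (anyNA(score) || anyNA(label)) abort("scores and labels must be complete")
  if (!any(label) || all(label)) abort("both outcome classes must be present")
  s <- orient_scores(score, direction)
  u <- sort(unique(s))
  k <- length(u)
  thr <- c(-Inf, if (k > 1) (u[-1] + u[-k]) / 2, Inf)
  n1 <- sum(label)
  n0 <- sum(!label)
  # counts per distinct score, then cumulative sweeps over thresholds
  np <- rowsum(as.numeric(label), s)[, 1]
  nn <- rowsum(as.numeric(!label), s)[, 1]
  pos_ge <- rev(cumsum(rev(np)))   # cases with s >= u[j]
  neg_le <- cumsum(nn)             # controls with s <= u[j]
  sens <- c(1, if (k > 1) pos_ge[2:k] / n1, 0)
  spec <- c(0, if (k > 1) neg_le[seq_len(k - 1)] / n0, 1)
  pl <- delong_placements(s, label)
  auc <- auc_mw(s, label)
  auc_se <- sqrt(var(pl$v10) / n1 + var(pl$v01) / n0)
  cutoff <- if (direction == "lower_risk") -thr else thr
  structure(list(curve = data.frame(cutoff = cutoff, sensitivity = sens,
                                    specificity = spec),
                 auc = auc, auc_se = auc_se, direction = direction,
                 n_pos = n1, n_neg = n0,
                 oriented_score = s, label = label),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  ci <- x$auc + c(-1, 1) * 1.96 * x$auc_se
  cat(sprintf("ROC curve (%d cases / %d controls, direction: %s)\n",
              x$n_pos, x$n_neg, x$direction))
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f)\n", x$auc,
              max(0, ci[1]), min(1, ci[2])))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(1 - x$curve$specificity, x$curve$sensitivity, type = "l",
       xlab = "1 - specificity", ylab = "Sensitivity",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  abline(0, 1, col = "grey70", lty = 3)
  invisible(x)
}

#' Youden-optimal operating point
#'
#' Scans every ROC threshold for the maximum Youden index
#' `J = sensitivity + specificity - 1`; ties are broken toward the cutoff
#' with higher specificity. Predictive values come from the 2x2 table at the
#' chosen cutoff.
#'
#' @param roc an object from [roc_curve()].
#' @return an object of class `operating_point`: `cutoff` (original score
#'   scale), `sensitivity`, `specificity`, `ppv`, `npv` (all percent) and
#'   `youden_j` (proportion scale).
#' @export
youden_optimal <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  cv <- roc$curve
  j <- cv$sensitivity + cv$specificity - 1
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[which.max(cv$specificity[best])]
  # confusion table at the chosen threshold (oriented scale)
  thr <- if (roc$direction == "lower_risk") -cv$cutoff[best] else
    cv$cutoff[best]
  pos_call <- roc$oriented_score >= thr
  tp <- sum(pos_call & roc$label)
  fp <- sum(pos_call & !roc$label)
  tn <- sum(!pos_call & !roc$label)
  fn <- sum(!pos_call & roc$label)
  structure(list(cutoff = cv$cutoff[best],
                 sensitivity = 100 * cv$sensitivity[best],
                 specificity = 100 * cv$specificity[best],
                 ppv = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
                 npv = if (tn + fn > 0) 100 * tn / (tn + fn) else NA_real_,
                 youden_j = j[best],
                 confusion = c(tp = tp, fp = fp, tn = tn, fn = fn)),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("Youden-optimal cutoff %.2f: J = %.3f\n", x$cutoff, x$youden_j))
  cat(sprintf("  sensitivity %.2f%%, specificity %.2f%%, PPV %.2f%%, NPV %.2f%%\n",
              x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}

#' Paired comparison of two AUCs (DeLong test)
#'
#' Compares the AUCs of two risk scores measured on the same subjects using
#' the DeLong placement-value covariance:
#' `z = (AUC1 - AUC2) / sqrt(var(AUC1) + var(AUC2) - 2 cov)`, with a
#' two-sided normal p value. Identical AUCs give `z = 0`, `p = 1`; a zero
#' variance with a nonzero difference is flagged degenerate (`NA` p).
#'
#' @param score1,score2 risk scores for the same subjects.
#' @param label shared binary outcome.
#' @param direction1,direction2 score orientations (see [roc_curve()]).
#' @return an object of class `auc_comparison`: `auc_1`, `auc_2`,
#'   `difference`, `z`, `p_two_sided`, `degenerate`.
#' @export
compare_auc_paired <- function(score1, score2, label,
                               direction1 = "higher_risk",
                               direction2 = "higher_risk") {
  label <- as.logical(label)
  stopifnot(length(score1) == length(label),
            length(score2) == length(label))
  if (!any(label) || all(label)) abort("both outcome classes must be present")
  s1 <- orient_scores(score1, match.arg(direction1,
                                        c("higher_risk", "lower_risk")))
  s2 <- orient_scores(score2, match.arg(direction2,
                                        c("higher_risk", "lower_risk")))
  n1 <- sum(label)
  n0 <- sum(!label)
  p1 <- delong_placements(s1, label)
  p2 <- delong_placements(s2, label)
  auc1 <- mean(p1$v10)
  auc2 <- mean(p2$v10)
  s10 <- cov(cbind(p1$v10, p2$v10))
  s01 <- cov(cbind(p1$v01, p2$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  diff <- auc1 - auc2
  if (abs(diff) < 1e-15) {
    z <- 0; p <- 1; degenerate <- FALSE
  } else if (var_diff <= 0) {
    z <- NA_real_; p <- NA_real_; degenerate <- TRUE
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
    degenerate <- FALSE
  }
  structure(list(auc_1 = auc1, auc_2 = auc2, difference = diff, z = z,
                 p_two_sided = p, degenerate = degenerate),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("Paired AUC comparison: %.3f vs %.3f (diff %.3f)\n",
              x$auc_1, x$auc_2, x$difference))
  if (x$degenerate) cat("  degenerate variance: no test statistic\n")
  else cat(sprintf("  z = %.3f, two-sided p = %.3g\n", x$z, x$p_two_sided))
  invisible(x)
}
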