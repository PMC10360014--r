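# Method-agreement statistics: estimated (device) vs reference VO2max.
# Sample statistics throughout (n - 1 denominators).

check_pairs <- function(est, ref, min_n = 2) {
  stopifnot(is.numeric(est), is.numeric(ref))
  if (length(est) != length(ref)) abort("est and ref must have equal lengths")
  if (length(est) < min_n) abort("need at least %d pairs", min_n)
  if (!all(is.finite(est)) || !all(is.finite(ref)))
    abort("est and ref must be finite")
  invisible(length(est))
}

#' Constant error
#'
#' Arithmetic mean (and sample SD) of the estimated-minus-reference
#' differences.
#'
#' @param est,ref paired measurement vectors (device estimate, reference).
#' @return `c(mean, sd)` of `est - ref`.
#' @export
constant_error <- function(est, ref) {
  check_pairs(est, ref)
  d <- est - ref
  c(mean = mean(d), sd = sd(d))
}

#' Paired t test of the constant error
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with `df = n - 1` and a two-sided p
#' from the t distribution; equivalent to a one-sample t test of the
#' differences.
#'
#' @inheritParams constant_error
#' @return list with `t`, `df`, `p`, and `degenerate` (`TRUE` when the
#'   differences have zero variance, in which case `t` and `p` are `NA`).
#' @export
paired_t <- function(est, ref) {
  n <- check_pairs(est, ref)
  ce <- constant_error(est, ref)
  if (ce["sd"] == 0)
    return(list(t = NA_real_, df = n - 1, p = NA_real_, degenerate = TRUE))
  t <- unname(ce["mean"] / (ce["sd"] / sqrt(n)))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1), degenerate = FALSE)
}

#' Pearson correlation and coefficient of determination
#'
#' @inheritParams constant_error
#' @return `c(r, r_squared)`.
#' @export
pearson_r2 <- function(est, ref) {
  check_pairs(est, ref, min_n = 3)
  if (sd(est) == 0 || sd(ref) == 0)
    abort("correlation undefined for zero-variance series")
  r <- cor(est, ref)
  c(r = r, r_squared = r^2)
}

#' Intraclass correlation for paired measurements
#'
#' Single-rater ICC from the two-way mean-squares decomposition with the two
#' methods as raters. The consistency form ignores a fixed offset between
#' methods; the absolute-agreement form penalises it:
#' \deqn{ICC(C,1) = (MSR - MSE) / (MSR + (k-1) MSE)}
#' \deqn{ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)}
#' with `k = 2` raters, `MSR` the between-subject, `MSC` the between-rater
#' and `MSE` the residual mean square.
#'
#' @inheritParams constant_error
#' @param form which form to return; by default both.
#' @return named numeric vector with `consistency` and/or
#'   `absolute_agreement` (`NA` with a warning when the mean squares are
#'   degenerate).
#' @export
icc_pair <- function(est, ref, form = c("both", "consistency",
                                        "absolute_agreement")) {
  form <- match.arg(form)
  n <- check_pairs(est, ref, min_n = 3)
  y <- cbind(est, ref)
  k <- 2
  row_m <- rowMeans(y)
  col_m <- colMeans(y)
  g <- mean(y)
  msr <- k * sum((row_m - g)^2) / (n - 1)
  msc <- n * sum((col_m - g)^2) / (k - 1)
  mse <- sum((y - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + g)^2) / ((n - 1) * (k - 1))
  denom_c <- msr + (k - 1) * mse
  denom_a <- msr + (k - 1) * mse + k * (msc - mse) / n
  out <- c(consistency = if (denom_c > 0) (msr - mse) / denom_c else NA_real_,
           absolute_agreement = if (denom_a > 0) (msr - mse) / denom_a
                                else NA_real_)
  if (anyNA(out)) warning("degenerate mean squares: ICC undefined")
  switch(form, both = out, consistency = out["consistency"],
         absolute_agreement = out["absolute_agreement"])
}

#' Mean absolute error and mean absolute percentage error
#'
#' MAPE uses the reference (gold-standard) value as the denominator.
#'
#' @inheritParams constant_error
#' @return `c(mae, mape_pct)` with MAPE in percent.
#' @export
mae_mape <- function(est, ref) {
  check_pairs(est, ref, min_n = 1)
  if (any(ref <= 0)) abort("reference values must be positive for MAPE")
  c(mae = mean(abs(est - ref)),
    mape_pct = 100 * mean(abs(est - ref) / ref))
}

#' Bland-Altman limits of agreement
#'
#' Bias is the constant error mean; the 95% limits of agreement are
#' `bias +/- 1.96 * sd` of the differences (the conventional 1.96 constant,
#' not an exact t quantile).
#'
#' @inheritParams constant_error
#' @return list with `bias`, `loa_lower`, `loa_upper`, `loa_width`.
#' @export
bland_altman <- function(est, ref) {
  check_pairs(est, ref)
  ce <- constant_error(est, ref)
  list(bias = unname(ce["mean"]),
       loa_lower = unname(ce["mean"] - 1.96 * ce["sd"]),
       loa_upper = unname(ce["mean"] + 1.96 * ce["sd"]),
       loa_width = unname(2 * 1.96 * ce["sd"]))
}

#' Method-agreement report
#'
#' Computes the full agreement panel between a device estimate and a
#' reference measurement: constant error (mean, SD), paired t test, Pearson
#' r and r^2, both ICC forms, MAE/MAPE and Bland-Altman limits of agreement.
#'
#' @inheritParams constant_error
#' @return an object of class `vo2_agreement` (a list of all statistics,
#'   plus `n`); supports `print()` and `plot()` (Bland-Altman plot).
#' @examples
#' coh <- simulate_cohort(cohort_config(n_participants = 46, seed = 1))
#' vo2_agreement(coh$vo2max_swt, coh$vo2max_cpet)
#' @export
vo2_agreement <- function(est, ref) {
  n <- check_pairs(est, ref, min_n = 3)
  ce <- constant_error(est, ref)
  tt <- paired_t(est, ref)
  r <- pearson_r2(est, ref)
  icc <- icc_pair(est, ref)
  acc <- mae_mape(est, ref)
  ba <- bland_altman(est, ref)
  structure(list(n = n, est = est, ref = ref,
                 ce_mean = unname(ce["mean"]), ce_sd = unname(ce["sd"]),
                 t_stat = tt$t, df = tt$df, p_two_sided = tt$p,
                 pearson_r = unname(r["r"]),
                 r_squared = unname(r["r_squared"]),
                 icc_consistency = unname(icc["consistency"]),
                 icc_absolute = unname(icc["absolute_agreement"]),
                 mae = unname(acc["mae"]), mape_pct = unname(acc["mape_pct"]),
                 bias = ba$bias, loa_lower = ba$loa_lower,
                 loa_upper = ba$loa_upper, loa_width = ba$loa_width),
            class = "vo2_agreement")
}

#' @export
print.vo2_agreement <- function(x, ...) {
  cat(sprintf("Method agreement on %d pairs (estimate vs reference):\n", x$n))
  cat(sprintf("  constant error: %.2f (SD %.2f); t(%d) = %.2f, p = %.3g\n",
              x$ce_mean, x$ce_sd, x$df, x$t_stat, x$p_two_sided))
  cat(sprintf("  Pearson r = %.3f (r^2 = %.3f); ICC consistency %.3f, absolute %.3f\n",
              x$pearson_r, x$r_squared, x$icc_consistency, x$icc_absolute))
  cat(sprintf("  MAE = %.3f, MAPE = %.2f%%\n", x$mae, x$mape_pct))
  cat(sprintf("  Bland-Altman: bias %.2f, 95%% LoA [%.2f, %.2f] (width %.2f)\n",
              x$bias, x$loa_lower, x$loa_upper, x$loa_width))
  invisible(x)
}

#' @export
plot.vo2_agreement <- function(x, ...) {
  m <- (x$est + x$ref) / 2
  d <- x$est - x$ref
  plot(m, d, pch = 19, col = "steelblue",
       xlab = "Mean of methods", ylab = "Difference (estimate - reference)",
       ylim = range(c(d, x$loa_lower, x$loa_upper)), ...)
  abline(h = x$bias, col = "grey20")
  abline(h = c(x$loa_lower, x$loa_upper), col = "grey40", lty = 2)
  abline(h = 0, col = "grey70", lty = 3)
  invisible(x)
}

#' @export
as.data.frame.vo2_agreement <- function(x, ...) {
  fields <- setdiff(names(x), c("est", "ref"))
  as.data.frame(x[fields])
}
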