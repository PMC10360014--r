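#' Odds ratio from a 2x2 table
#'
#' Cross-product odds ratio with a Woolf (log-OR) 95% confidence interval:
#' `OR = ad/bc`, `SE(log OR) = sqrt(1/a + 1/b + 1/c + 1/d)`,
#' `CI = exp(log OR +/- 1.96 SE)`. With any zero cell the Haldane-Anscombe
#' correction (0.5 added to every cell) is applied and flagged.
#'
#' @param a exposed cases, or a 2x2 matrix `rbind(c(a, b), c(c, d))`.
#' @param b exposed non-cases.
#' @param c unexposed cases.
#' @param d unexposed non-cases.
#' @return an object of class `or_result`: `or`, `ci_low`, `ci_high`,
#'   `log_or_se`, `haldane` (correction applied), and the cell counts.
#' @examples
#' odds_ratio_2x2(14, 13, 6, 13)  # OR 2.333 (0.684-7.960)
#' @export
odds_ratio_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || anyNA(cells)) abort("cell counts must be nonnegative")
  haldane <- any(cells == 0)
  x <- if (haldane) cells + 0.5 else cells
  or <- (x["a"] * x["d"]) / (x["b"] * x["c"])
  se <- sqrt(sum(1 / x))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  structure(list(or = unname(or), ci_low = ci[1], ci_high = ci[2],
                 log_or_se = unname(se), haldane = haldane,
                 cells = cells),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR %.3f (95%% CI %.3f-%.3f)%s\n", x$or, x$ci_low, x$ci_high,
              if (x$haldane) " [Haldane-Anscombe 0.5 correction]" else ""))
  invisible(x)
}

#' Build a 2x2 table from an exposure and an outcome
#'
#' Counts `a` = exposed cases, `b` = exposed non-cases, `c` = unexposed
#' cases, `d` = unexposed non-cases. `exposed_level` selects which level of
#' a factor/character exposure counts as exposed, making the indicator
#' coding explicit.
#'
#' @param exposure logical vector, or factor/character with
#'   `exposed_level` naming the indicator level.
#' @param outcome logical (or 0/1) outcome vector.
#' @param exposed_level the exposure level treated as exposed.
#' @return a 2x2 integer matrix suitable for [odds_ratio_2x2()].
#' @export
two_by_two <- function(exposure, outcome, exposed_level = NULL) {
  if (!is.logical(exposure)) {
    if (is.null(exposed_level))
      abort("non-logical exposure needs an explicit exposed_level")
    exposure <- exposure == exposed_level
  }
  outcome <- as.logical(outcome)
  if (length(exposure) != length(outcome)) abort("length mismatch")
  m <- matrix(c(sum(exposure & outcome), sum(exposure & !outcome),
                sum(!exposure & outcome), sum(!exposure & !outcome)),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("exposed", "unexposed"),
                              c("case", "noncase")))
  m
}
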