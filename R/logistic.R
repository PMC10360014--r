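#' Binomial logistic regression with per-unit odds ratios
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' [stats::glm()]) with Wald standard errors, per-unit odds ratios and 95%
#' Wald confidence intervals (`exp(coef +/- 1.96 se)`). Complete or
#' quasi-complete separation is detected (fitted probabilities pinned to 0/1
#' together with runaway coefficients); when flagged, Wald CIs are not
#' reported.
#'
#' @param formula model formula, e.g. `ams ~ vo2max_swt + rdw_cv`.
#' @param data a `data.frame` (e.g. a [simulate_cohort()] table).
#' @return an object of class `ams_logistic`: `fit` (the `glm`), `or_table`
#'   (term, coef, se, or, ci_low, ci_high, p), `log_lik`, `converged`,
#'   `separated`, `n`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_participants = 200, seed = 3))
#' fit_logistic(ams ~ vo2max_swt + rdw_cv, coh)
#' @export
fit_logistic <- function(formula, data) {
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  if (length(unique(y)) < 2) abort("outcome must not be constant")
  if (nrow(mf) <= ncol(mf)) abort("need more observations than parameters")
  fit <- suppressWarnings(glm(formula, data = data, family = binomial()))
  p <- fitted(fit)
  eps <- 1e-8
  separated <- (any(p < eps) || any(p > 1 - eps)) &&
    max(abs(coef(fit))) > 10
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- cf / se
  tab <- data.frame(term = names(cf), coef = unname(cf), se = unname(se),
                    or = exp(unname(cf)),
                    ci_low = exp(unname(cf) - 1.96 * unname(se)),
                    ci_high = exp(unname(cf) + 1.96 * unname(se)),
                    p = 2 * pnorm(-abs(unname(z))))
  if (separated) tab[, c("se", "ci_low", "ci_high", "p")] <- NA_real_
  structure(list(fit = fit, or_table = tab,
                 log_lik = as.numeric(logLik(fit)),
                 converged = isTRUE(fit$converged) && !separated,
                 separated = separated, n = nrow(mf)),
            class = "ams_logistic")
}

#' @export
print.ams_logistic <- function(x, ...) {
  cat(sprintf("Logistic risk model (n = %d, logLik = %.2f%s)\n", x$n,
              x$log_lik,
              if (x$separated) ", SEPARATION DETECTED - Wald CIs suppressed"
              else ""))
  tab <- x$or_table
  tab[, -1] <- lapply(tab[, -1], function(v) signif(v, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ams_logistic <- function(object, ...) coef(object$fit)

#' @export
#' @method predict ams_logistic
predict.ams_logistic <- function(object, newdata = NULL,
                                 type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) predict(object$fit, type = type)
  else predict(object$fit, newdata = newdata, type = type)
}

#' Combined-model risk score
#'
#' The fitted linear predictor of a logistic model, used as the ROC score of
#' a combined (multi-predictor) model. Rows with missing predictor values
#' are rejected with a message naming them.
#'
#' @param model an [fit_logistic()] result.
#' @param rows a `data.frame` with the model's predictor columns.
#' @return numeric score vector (log-odds scale), one per row.
#' @export
combined_model_score <- function(model, rows) {
  stopifnot(inherits(model, "ams_logistic"), is.data.frame(rows))
  vars <- attr(terms(model$fit), "term.labels")
  missing_vars <- setdiff(vars, names(rows))
  if (length(missing_vars))
    abort("missing predictor column(s): %s",
          paste(missing_vars, collapse = ", "))
  bad <- which(!complete.cases(rows[, vars, drop = FALSE]))
  if (length(bad))
    abort("missing predictor values in row(s): %s",
          paste(bad, collapse = ", "))
  unname(predict(model$fit, newdata = rows, type = "link"))
}
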