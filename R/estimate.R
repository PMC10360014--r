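#' Estimate VO2max from weighted segments
#'
#' Fits a weighted least-squares line of theoretical VO2 on mean segment
#' heart rate and reads it off at maximum heart rate: at HRmax the oxygen
#' cost the participant could just sustain is, by definition, VO2max. The
#' result is rounded half-up to an integer, matching device output
#' granularity.
#'
#' @param segments weighted segments from [weight_segments()].
#' @param profile a [participant_profile()] (supplies `hr_max`).
#' @param config an [swt_config()].
#' @param hr_max overrides the profile's maximum heart rate.
#' @return a list of class `vo2max_estimate` with `vo2max` (integer, `NA`
#'   when no reliable data), `slope`, `intercept`, `fit` (the `lm`),
#'   `n_segments` and `quality` (`"ok"`, `"low_segments"`, or
#'   `"no_reliable_data"`).
#' @export
estimate_vo2max <- function(segments, profile, config = swt_config(),
                            hr_max = NULL) {
  stopifnot(is.data.frame(segments), inherits(profile, "participant_profile"))
  if (is.null(hr_max)) hr_max <- profile$hr_max
  out <- list(vo2max = NA_real_, slope = NA_real_, intercept = NA_real_,
              fit = NULL, n_segments = nrow(segments),
              hr_max = hr_max, quality = "no_reliable_data")
  class(out) <- "vo2max_estimate"
  if (nrow(segments) < 2 || length(unique(segments$mean_hr)) < 2)
    return(out)
  if (all(is.na(segments$weight)))
    segments$weight <- rep(1 / nrow(segments), nrow(segments))
  fit <- lm(theoretical_vo2 ~ mean_hr, data = segments,
            weights = segments$weight)
  cf <- coef(fit)
  raw <- unname(cf[1] + cf[2] * hr_max)
  out$fit <- fit
  out$intercept <- unname(cf[1])
  out$slope <- unname(cf[2])
  out$vo2max <- round_half_up(raw)
  out$quality <- if (nrow(segments) >= config$min_segments &&
                     out$vo2max >= 10 && out$vo2max <= 90) "ok"
                 else "low_segments"
  out
}

#' Smartwatch VO2max estimation from a run session
#'
#' The full submaximal estimation pipeline: centred moving-average filtering
#' of heart rate and speed, selection of samples where both increase,
#' artifact exclusion (downhill pattern, heart-rate rise at zero speed,
#' short high-intensity bursts), heart-rate-zone segmentation with a drift
#' cap, duration/zone weighting, and a weighted linear fit of theoretical
#' VO2 (`3.5 * speed` km/h) on mean segment heart rate, extrapolated to
#' maximum heart rate. Deterministic for fixed input and configuration.
#'
#' @param session a [run_session()].
#' @param config an [swt_config()].
#' @param hr_max maximum heart rate anchor for the extrapolation; defaults
#'   to the profile's value (itself defaulting to `220 - age`).
#' @return an object of class `swt_vo2max`: the [estimate_vo2max()] fields
#'   plus `segments`, `excluded_spans`, `session` and `config`. Supports
#'   `print()`, `summary()`, `coef()`, `predict()`, `fitted()`,
#'   `residuals()` and `plot()`.
#' @examples
#' p <- participant_profile("p1", 35, "female", 165, 60, hr_rest = 68,
#'                          true_vo2max = 35)
#' ses <- simulate_run_session(p, scenario_clean_ramp(), seed = 7)
#' fit <- swt_vo2max(ses)
#' fit
#' @export
swt_vo2max <- function(session, config = swt_config(), hr_max = NULL) {
  stopifnot(inherits(session, "run_session"), inherits(config, "swt_config"))
  if (is.null(hr_max)) hr_max <- session$profile$hr_max
  hr_f <- moving_average(session$hr_bpm, config$ma_window)
  speed_f <- moving_average(session$speed_kmh, config$ma_window)
  mask <- detect_activity(hr_f, speed_f)
  excl <- apply_exclusions(session, mask, config, hr_max = hr_max)
  segments <- segment_by_zone(session, excl$mask, hr_max = hr_max,
                              config = config)
  if (nrow(segments) > 0) segments <- weight_segments(segments, config)
  est <- estimate_vo2max(segments, session$profile, config, hr_max = hr_max)
  est$segments <- segments
  est$excluded_spans <- excl$excluded_spans
  est$session <- session
  est$config <- config
  class(est) <- c("swt_vo2max", "vo2max_estimate")
  est
}

#' @rdname swt_vo2max
#' @param ... passed on (unused).
#' @export
run_swt_pipeline <- function(session, config = swt_config(), hr_max = NULL,
                             ...) {
  swt_vo2max(session, config = config, hr_max = hr_max)
}

#' @export
print.vo2max_estimate <- function(x, ...) {
  if (x$quality == "no_reliable_data") {
    cat("Smartwatch VO2max estimate: no reliable data",
        sprintf("(%d usable segment(s))\n", x$n_segments))
    return(invisible(x))
  }
  cat(sprintf("Smartwatch VO2max estimate: %d mL/kg/min (quality: %s)\n",
              as.integer(x$vo2max), x$quality))
  cat(sprintf("  %d segments; VO2 = %.3f + %.4f x HR, read at HRmax = %g bpm\n",
              x$n_segments, x$intercept, x$slope, x$hr_max))
  invisible(x)
}

#' @export
summary.swt_vo2max <- function(object, ...) {
  print(object)
  if (nrow(object$segments) > 0) {
    cat("\nReliable segments:\n")
    print(format(object$segments[, c("start", "end", "duration", "zone",
                                     "mean_hr", "mean_speed",
                                     "theoretical_vo2", "weight")],
                 digits = 4), row.names = FALSE)
  }
  if (nrow(object$excluded_spans) > 0) {
    cat("\nExcluded spans:\n")
    print(object$excluded_spans, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.vo2max_estimate <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
#' @method predict vo2max_estimate
predict.vo2max_estimate <- function(object, hr = NULL, ...) {
  if (is.null(object$fit)) abort("no fitted line: no reliable data")
  if (is.null(hr)) hr <- object$hr_max
  object$intercept + object$slope * hr
}

#' @export
fitted.swt_vo2max <- function(object, ...) {
  if (is.null(object$fit)) abort("no fitted line: no reliable data")
  fitted(object$fit)
}

#' @export
residuals.swt_vo2max <- function(object, ...) {
  if (is.null(object$fit)) abort("no fitted line: no reliable data")
  residuals(object$fit)
}

#' @export
plot.swt_vo2max <- function(x, ...) {
  if (nrow(x$segments) == 0) abort("nothing to plot: no reliable segments")
  s <- x$segments
  hr_range <- range(c(s$mean_hr, x$hr_max))
  plot(s$mean_hr, s$theoretical_vo2,
       cex = 0.5 + 3 * s$weight, pch = 19, col = "steelblue",
       xlim = hr_range,
       ylim = range(c(s$theoretical_vo2, x$vo2max), na.rm = TRUE),
       xlab = "Mean segment heart rate (bpm)",
       ylab = expression(paste("Theoretical VO"[2],
                               " (mL kg"^-1, " min"^-1, ")")), ...)
  if (!is.null(x$fit)) {
    abline(x$intercept, x$slope, col = "grey40")
    points(x$hr_max, predict(x), pch = 4, col = "firebrick", cex = 1.5)
    text(x$hr_max, predict(x), labels = sprintf("VO2max = %d", x$vo2max),
         pos = 2, col = "firebrick")
  }
  invisible(x)
}
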