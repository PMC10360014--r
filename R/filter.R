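#' Centred moving average with shrinking edges
#'
#' Smooths a series with a centred window; near the edges the window shrinks
#' so the output has the same length as the input. A window of 1 sample is
#' the identity.
#'
#' @param series numeric series (finite values).
#' @param window window length in samples (at 1 Hz, seconds).
#' @return the filtered series, same length as `series`.
#' @examples
#' moving_average(c(0, 0, 3, 0, 0), 3)  # 0 1 1 1 0
#' @export
moving_average <- function(series, window) {
  if (length(series) == 0) abort("cannot filter an empty series")
  if (!all(is.finite(series))) abort("series must be finite")
  window <- as.integer(window)
  if (window < 1) abort("window must be at least 1 sample")
  n <- length(series)
  half_l <- (window - 1L) %/% 2L
  half_r <- window %/% 2L
  cs <- cumsum(c(0, series))
  i <- seq_len(n)
  lo <- pmax(1L, i - half_l)
  hi <- pmin(n, i + half_r)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect active effort samples
#'
#' A sample counts as active effort only when both the filtered heart rate
#' and the filtered speed are increasing, i.e. both first differences are
#' strictly positive. The first sample is always `FALSE` (no difference is
#' defined there).
#'
#' @param hr_f filtered heart-rate series.
#' @param speed_f filtered speed series, same length.
#' @return a logical mask of the same length.
#' @export
detect_activity <- function(hr_f, speed_f) {
  if (length(hr_f) != length(speed_f))
    abort("hr_f and speed_f must have equal lengths")
  if (length(hr_f) < 2) abort("need at least 2 samples to differentiate")
  c(FALSE, diff(hr_f) > 0 & diff(speed_f) > 0)
}
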