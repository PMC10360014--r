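#' Theoretical oxygen cost of level running
#'
#' Imputes oxygen uptake from running speed: `3.5 * speed` mL·kg^-1·min^-1
#' for speed in km/h.
#'
#' @param speed speed in km/h, nonnegative.
#' @return theoretical VO2 in mL·kg^-1·min^-1.
#' @examples
#' theoretical_vo2(10)  # 35
#' @export
theoretical_vo2 <- function(speed) {
  stopifnot(is.numeric(speed))
  if (any(speed < 0)) abort("speed must be nonnegative")
  3.5 * speed
}

# zone id (1-based band index) per sample, NA outside the zone grid
hr_zone <- function(hr, hr_max, zone_breaks) {
  pct <- 100 * hr / hr_max
  z <- findInterval(pct, zone_breaks, rightmost.closed = TRUE)
  z[z < 1 | z >= length(zone_breaks)] <- NA_integer_
  z
}

#' Segment a run into reliable heart-rate-zone stretches
#'
#' Scans the selected (masked-in) samples for maximal stretches that stay in
#' one heart-rate zone with at most `hr_drift_max` bpm of drift. Stretches
#' shorter than `seg_min_s` are dropped; stretches reaching `seg_max_s` are
#' split. Zones are bands of percent-of-maximum heart rate (see
#' [swt_config()]); samples below the lowest band are never reliable.
#' Segment statistics are taken on the filtered series.
#'
#' @param session a [run_session()].
#' @param mask logical mask of selected samples (after exclusions).
#' @param hr_max maximum heart rate in bpm; defaults to the profile's value.
#' @param config an [swt_config()].
#' @return a `data.frame` with one row per segment: `start`, `end` (1-based
#'   inclusive sample indices), `duration`, `mean_hr`, `hr_drift`,
#'   `mean_speed`, `zone`, `theoretical_vo2` and a `weight` placeholder
#'   (`NA` until [weight_segments()]).
#' @export
segment_by_zone <- function(session, mask, hr_max = NULL,
                            config = swt_config()) {
  stopifnot(inherits(session, "run_session"), is.logical(mask))
  if (is.null(hr_max)) hr_max <- session$profile$hr_max
  stopifnot(is_scalar_num(hr_max), hr_max > 0)
  hr_f <- moving_average(session$hr_bpm, config$ma_window)
  speed_f <- moving_average(session$speed_kmh, config$ma_window)
  zone <- hr_zone(hr_f, hr_max, config$zone_breaks)
  ok <- mask & !is.na(zone)
  dt <- if (length(session$t) > 1) session$t[2] - session$t[1] else 1

  segs <- list()
  close_seg <- function(i0, i1) {
    dur <- (i1 - i0 + 1) * dt
    if (dur < config$seg_min_s) return(NULL)
    idx <- i0:i1
    ms <- mean(speed_f[idx])
    data.frame(start = i0, end = i1, duration = dur,
               mean_hr = mean(hr_f[idx]),
               hr_drift = max(hr_f[idx]) - min(hr_f[idx]),
               mean_speed = ms, zone = zone[i0],
               theoretical_vo2 = theoretical_vo2(ms),
               weight = NA_real_)
  }

  i0 <- NA_integer_; lo <- Inf; hi <- -Inf
  for (i in seq_along(ok)) {
    if (ok[i]) {
      if (is.na(i0)) { i0 <- i; lo <- hr_f[i]; hi <- hr_f[i]; next }
      new_lo <- min(lo, hr_f[i]); new_hi <- max(hi, hr_f[i])
      same_zone <- !is.na(zone[i]) && zone[i] == zone[i0]
      within_drift <- (new_hi - new_lo) <= config$hr_drift_max
      within_len <- (i - i0 + 1) * dt <= config$seg_max_s
      if (same_zone && within_drift && within_len) {
        lo <- new_lo; hi <- new_hi
      } else {
        segs[[length(segs) + 1]] <- close_seg(i0, i - 1L)
        i0 <- i; lo <- hr_f[i]; hi <- hr_f[i]
      }
    } else if (!is.na(i0)) {
      segs[[length(segs) + 1]] <- close_seg(i0, i - 1L)
      i0 <- NA_integer_
    }
  }
  if (!is.na(i0)) segs[[length(segs) + 1]] <- close_seg(i0, length(ok))
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (length(segs) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      duration = numeric(0), mean_hr = numeric(0),
                      hr_drift = numeric(0), mean_speed = numeric(0),
                      zone = integer(0), theoretical_vo2 = numeric(0),
                      weight = numeric(0)))
  do.call(rbind, segs)
}

#' Weight reliable segments
#'
#' Each segment's raw weight is its duration times a duration-preference
#' factor (1 inside the preferred 30 s–4 min window, `nonpreferred_weight`
#' outside) times a zone factor that up-weights higher-intensity zones
#' linearly (`1 + zone_weight_step * (zone - 1)`). Weights are normalised to
#' sum to 1. This is a documented approximation of the device's proprietary
#' weighting rule.
#'
#' @param segments a segment `data.frame` from [segment_by_zone()].
#' @param config an [swt_config()].
#' @return the segments with the `weight` column filled in.
#' @export
weight_segments <- function(segments, config = swt_config()) {
  stopifnot(is.data.frame(segments))
  if (nrow(segments) == 0) abort("cannot weight an empty segment list")
  pref <- segments$duration >= config$preferred_min_s &
          segments$duration <= config$preferred_max_s
  w <- segments$duration *
       ifelse(pref, 1, config$nonpreferred_weight) *
       (1 + config$zone_weight_step * (segments$zone - 1))
  segments$weight <- w / sum(w)
  segments
}
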