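#' Estimator configuration
#'
#' All thresholds of the smartwatch VO2max pipeline in one place. Defaults
#' follow conventional exercise-physiology practice where the underlying
#' device algorithm leaves them unstated.
#'
#' @param ma_window centred moving-average window for heart rate and speed,
#'   seconds (default 5: suppresses sample noise at 1 Hz without smearing
#'   20 s segments).
#' @param seg_min_s,seg_max_s admissible segment duration, s (20–600).
#' @param preferred_min_s,preferred_max_s preferred segment duration window,
#'   s (30–240); segments outside it are down-weighted.
#' @param hr_drift_max maximum heart-rate drift (max minus min) within a
#'   segment, bpm (default 5, the "small heart rate change" level).
#' @param zone_breaks heart-rate zone edges as percent of maximum heart
#'   rate. Default `c(50, 60, 70, 80, 90, 100)`: five conventional bands;
#'   samples below 50% HRmax are never considered reliable.
#' @param zone_weight_step linear up-weighting per zone above the first
#'   (default 0.25, so zones 1..5 get factors 1, 1.25, ..., 2).
#' @param nonpreferred_weight multiplicative down-weight for segments
#'   outside the preferred duration window (default 0.5).
#' @param min_segments minimum number of segments for an `ok`-quality
#'   estimate (default 3).
#' @param rule1_drop_bpm,rule1_window_s,rule1_min_speed downhill-pattern
#'   exclusion: filtered heart rate falls by at least `rule1_drop_bpm` over
#'   `rule1_window_s` seconds while filtered speed stays at or above
#'   `rule1_min_speed` km/h.
#' @param rule2_rise_bpm,rule2_min_s,rule2_max_speed sudden-stop exclusion:
#'   heart rate rises by at least `rule2_rise_bpm` over a standstill
#'   (filtered speed below `rule2_max_speed` km/h) lasting at least
#'   `rule2_min_s` seconds.
#' @param rule3_max_s,rule3_slope short-high-intensity exclusion: top-zone
#'   spans shorter than `rule3_max_s` seconds with mean heart-rate slope
#'   above `rule3_slope` bpm/s.
#' @return an object of class `swt_config` (a validated list).
#' @export
swt_config <- function(ma_window = 5,
                       seg_min_s = 20, seg_max_s = 600,
                       preferred_min_s = 30, preferred_max_s = 240,
                       hr_drift_max = 5,
                       zone_breaks = c(50, 60, 70, 80, 90, 100),
                       zone_weight_step = 0.25,
                       nonpreferred_weight = 0.5,
                       min_segments = 3,
                       rule1_drop_bpm = 5, rule1_window_s = 10,
                       rule1_min_speed = 6,
                       rule2_rise_bpm = 5, rule2_min_s = 10,
                       rule2_max_speed = 0.5,
                       rule3_max_s = 20, rule3_slope = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$ma_window >= 1, cfg$seg_min_s >= 1,
            cfg$seg_max_s > cfg$seg_min_s,
            cfg$hr_drift_max > 0, length(cfg$zone_breaks) >= 2,
            !is.unsorted(cfg$zone_breaks, strictly = TRUE),
            cfg$min_segments >= 2, cfg$nonpreferred_weight > 0)
  structure(cfg, class = "swt_config")
}

#' @export
print.swt_config <- function(x, ...) {
  cat("SWT estimator configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm,
                                   paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}
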