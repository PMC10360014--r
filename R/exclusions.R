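# Artifact exclusion rules. All three detectors work on the filtered series
# and return spans as 1-based inclusive [start, end] sample indices.

# rolling minimum over a forward window of k+1 samples starting at i
roll_min_fwd <- function(x, k) {
  n <- length(x)
  m <- n - k
  if (m < 1) return(numeric(0))
  vapply(seq_len(m), function(i) min(x[i:(i + k)]), numeric(1))
}

# collapse a logical flag vector into spans
flag_spans <- function(flag, reason) {
  runs <- true_runs(flag)
  if (nrow(runs) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      reason = character(0)))
  data.frame(start = runs$start, end = runs$end, reason = reason)
}

detect_rule1_downhill <- function(hr_f, speed_f, cfg) {
  n <- length(hr_f)
  k <- as.integer(cfg$rule1_window_s)
  flag <- logical(n)
  if (n > k) {
    drop <- hr_f[seq_len(n - k)] - hr_f[seq_len(n - k) + k]
    fast <- roll_min_fwd(speed_f, k) >= cfg$rule1_min_speed
    hit <- which(drop >= cfg$rule1_drop_bpm & fast)
    for (i in hit) flag[i:(i + k)] <- TRUE
  }
  flag_spans(flag, "downhill_pattern")
}

detect_rule2_stop_rise <- function(hr_f, speed_f, cfg) {
  flag <- logical(length(hr_f))
  stopped <- true_runs(speed_f < cfg$rule2_max_speed)
  for (r in seq_len(nrow(stopped))) {
    i0 <- stopped$start[r]; i1 <- stopped$end[r]
    if (i1 - i0 + 1 < cfg$rule2_min_s) next
    h <- hr_f[i0:i1]
    # largest rise from any earlier sample to any later one within the run
    if (max(h - cummin(h)) >= cfg$rule2_rise_bpm) flag[i0:i1] <- TRUE
  }
  flag_spans(flag, "hr_rise_at_zero_speed")
}

detect_rule3_sprint <- function(hr_f, hr_max, cfg) {
  flag <- logical(length(hr_f))
  zb <- cfg$zone_breaks
  top_lo <- zb[length(zb) - 1] / 100 * hr_max
  runs <- true_runs(hr_f >= top_lo)
  for (r in seq_len(nrow(runs))) {
    i0 <- runs$start[r]; i1 <- runs$end[r]
    len <- i1 - i0 + 1
    if (len >= cfg$rule3_max_s || len < 2) next
    # rise rate into the span's peak: endpoint-to-endpoint slope would be
    # ~0 for a spike that rises and falls within the span
    im <- i0 - 1 + which.max(hr_f[i0:i1])
    slope <- if (im > i0) (hr_f[im] - hr_f[i0]) / (im - i0) else 0
    if (slope > cfg$rule3_slope) flag[i0:i1] <- TRUE
  }
  flag_spans(flag, "short_high_intensity")
}

#' Exclude artifact spans from the activity mask
#'
#' Applies the three artifact rules to a session: (1) `downhill_pattern` — a
#' significant heart-rate decrease while running fast, the signature of a
#' steep-downhill or soft-surface stretch where speed no longer reflects
#' oxygen demand; (2) `hr_rise_at_zero_speed` — heart rate climbing during a
#' standstill (a sudden stop mid-run); (3) `short_high_intensity` — a brief
#' top-zone burst with steeply rising heart rate (insufficient, anaerobic
#' effort). Flagged spans are removed from the mask and reported. Thresholds
#' come from [swt_config()].
#'
#' Note the downhill rule is triggered on heart-rate/speed discordance only:
#' stride-pattern information is not available from heart rate and speed
#' alone.
#'
#' @param session a [run_session()].
#' @param mask logical activity mask from [detect_activity()].
#' @param config an [swt_config()].
#' @param hr_max maximum heart rate used for the top-zone rule; defaults to
#'   the session profile's value.
#' @return a list with `mask` (the pruned mask) and `excluded_spans`
#'   (a `data.frame` with 1-based inclusive `start`, `end` and `reason`).
#' @export
apply_exclusions <- function(session, mask, config = swt_config(),
                             hr_max = NULL) {
  stopifnot(inherits(session, "run_session"), is.logical(mask),
            length(mask) == length(session$hr_bpm))
  if (is.null(hr_max)) hr_max <- session$profile$hr_max
  hr_f <- moving_average(session$hr_bpm, config$ma_window)
  speed_f <- moving_average(session$speed_kmh, config$ma_window)
  spans <- rbind(detect_rule1_downhill(hr_f, speed_f, config),
                 detect_rule2_stop_rise(hr_f, speed_f, config),
                 detect_rule3_sprint(hr_f, hr_max, config))
  for (r in seq_len(nrow(spans))) mask[spans$start[r]:spans$end[r]] <- FALSE
  list(mask = mask, excluded_spans = spans)
}
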