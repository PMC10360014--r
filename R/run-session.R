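#' Run session container
#'
#' A per-second heart-rate and speed trace from one outdoor run, plus the
#' participant profile. Time must be a strictly increasing uniform 1 Hz grid.
#'
#' @param t time in seconds (uniform grid, 1 s step).
#' @param hr_bpm heart rate series, bpm, each in \[30, 230\].
#' @param speed_kmh speed series, km/h, nonnegative.
#' @param profile a [participant_profile()].
#' @return an object of class `run_session`.
#' @export
run_session <- function(t, hr_bpm, speed_kmh, profile) {
  stopifnot(inherits(profile, "participant_profile"),
            is.numeric(t), is.numeric(hr_bpm), is.numeric(speed_kmh))
  n <- length(t)
  if (n < 2) abort("a run session needs at least 2 samples")
  if (length(hr_bpm) != n || length(speed_kmh) != n)
    abort("t, hr_bpm and speed_kmh must have equal lengths")
  if (anyNA(t) || anyNA(hr_bpm) || anyNA(speed_kmh))
    abort("run session series must be free of missing values")
  dt <- diff(t)
  if (any(dt <= 0)) abort("time must be strictly increasing")
  if (max(abs(dt - dt[1])) > 1e-6) abort("time grid must be uniform")
  if (any(speed_kmh < 0)) abort("speed must be nonnegative")
  if (any(hr_bpm < 30 | hr_bpm > 230))
    abort("heart rate must lie in [30, 230] bpm")
  structure(list(t = as.numeric(t), hr_bpm = as.numeric(hr_bpm),
                 speed_kmh = as.numeric(speed_kmh), profile = profile),
            class = "run_session")
}

#' @export
print.run_session <- function(x, ...) {
  cat(sprintf("Run session: %d samples (%.1f min) for participant %s\n",
              length(x$t), (max(x$t) - min(x$t)) / 60, x$profile$id))
  cat(sprintf("  HR %g-%g bpm, speed %.1f-%.1f km/h\n",
              min(x$hr_bpm), max(x$hr_bpm),
              min(x$speed_kmh), max(x$speed_kmh)))
  invisible(x)
}

#' @export
as.data.frame.run_session <- function(x, ...) {
  data.frame(t_s = x$t, hr_bpm = x$hr_bpm, speed_kmh = x$speed_kmh)
}

#' Run scenarios for the session simulator
#'
#' A scenario is an ordered table of phases. Effort fractions are fractions
#' of the participant's aerobic ceiling: a phase at effort `f` runs at speed
#' `f * true_vo2max / 3.5` km/h, whose steady-state heart rate is
#' `hr_rest + f * (hr_max - hr_rest)`.
#'
#' Phase types: `steady` (constant effort), `ramp` (linearly increasing
#' effort, the canonical clean protocol), `stop` (speed 0, heart rate decays
#' to rest), `stop_hr_rise` (speed 0 but heart rate keeps climbing — the
#' sudden-stop artifact), `downhill` (speed stays high while heart rate
#' falls — the steep-downhill artifact), and `sprint` (a short burst above
#' the aerobic ceiling with fast-rising heart rate).
#'
#' @param ... phase rows created by [phase_steady()], [phase_ramp()],
#'   [phase_stop()], [phase_stop_hr_rise()], [phase_downhill()],
#'   [phase_sprint()].
#' @return a `data.frame` of class `swt_scenario`.
#' @export
swt_scenario <- function(...) {
  phases <- rbind(...)
  stopifnot(is.data.frame(phases), nrow(phases) >= 1)
  if (any(phases$duration_s < 1)) abort("phase durations must be >= 1 s")
  class(phases) <- c("swt_scenario", "data.frame")
  phases
}

phase_row <- function(phase, duration_s, from = NA_real_, to = NA_real_,
                      param = NA_real_) {
  data.frame(phase = phase, duration_s = as.integer(duration_s),
             from = from, to = to, param = param)
}

#' @rdname swt_scenario
#' @param duration_s phase duration in seconds.
#' @param effort effort fraction in (0, 1.2\].
#' @export
phase_steady <- function(duration_s, effort)
  phase_row("steady", duration_s, from = effort, to = effort)

#' @rdname swt_scenario
#' @param from,to effort fractions at phase start and end.
#' @export
phase_ramp <- function(duration_s, from, to)
  phase_row("ramp", duration_s, from = from, to = to)

#' @rdname swt_scenario
#' @export
phase_stop <- function(duration_s) phase_row("stop", duration_s)

#' @rdname swt_scenario
#' @param rise_bpm total heart-rate rise forced over the phase (default 15).
#' @export
phase_stop_hr_rise <- function(duration_s, rise_bpm = 15)
  phase_row("stop_hr_rise", duration_s, param = rise_bpm)

#' @rdname swt_scenario
#' @param fall_bpm total heart-rate fall forced over the phase (default 20).
#' @export
phase_downhill <- function(duration_s, fall_bpm = 20)
  phase_row("downhill", duration_s, param = fall_bpm)

#' @rdname swt_scenario
#' @export
phase_sprint <- function(duration_s) phase_row("sprint", duration_s)

#' Prebuilt scenarios
#'
#' `scenario_clean_ramp()` is the canonical artifact-free protocol: a steady
#' warm-up (during which heart rate equilibrates; constant speed means those
#' samples are never selected) followed by a slow progressive ramp.
#' `scenario_with_artifacts()` embeds a sudden stop with rising heart rate, a
#' steep-downhill stretch and a short sprint into the same ramp.
#' `scenario_all_stop()` is the degenerate all-standstill input.
#'
#' @param warmup_s warm-up duration, s.
#' @param ramp_s ramp duration, s.
#' @param from,to effort fractions spanned by the ramp.
#' @return an `swt_scenario`.
#' @export
scenario_clean_ramp <- function(warmup_s = 120, ramp_s = 1200,
                                from = 0.45, to = 0.88) {
  swt_scenario(phase_steady(warmup_s, from), phase_ramp(ramp_s, from, to))
}

#' @rdname scenario_clean_ramp
#' @export
scenario_with_artifacts <- function(warmup_s = 120, ramp_s = 1200,
                                    from = 0.45, to = 0.80) {
  third <- round(ramp_s / 3)
  f1 <- from + (to - from) / 3
  f2 <- from + 2 * (to - from) / 3
  swt_scenario(
    phase_steady(warmup_s, from),
    phase_ramp(third, from, f1),
    phase_stop_hr_rise(60, rise_bpm = 15),
    phase_ramp(third, f1, f2),
    phase_downhill(40, fall_bpm = 24),
    phase_ramp(third, f2, to),
    phase_sprint(15)
  )
}

#' @rdname scenario_clean_ramp
#' @param duration_s total standstill duration, s.
#' @export
scenario_all_stop <- function(duration_s = 600) {
  swt_scenario(phase_stop(duration_s))
}

#' Simulate a run session
#'
#' Generates a 1 Hz heart-rate/speed trace for a scenario. During clean
#' phases heart rate follows the linear oxygen-demand relation
#' `HR = hr_rest + (hr_max - hr_rest) * (3.5 * speed / true_vo2max)` through a
#' first-order lag (time constant `lag_tau`, default 30 s). Artifact phases
#' deliberately break the coupling: `stop_hr_rise` forces heart rate up at
#' zero speed, `downhill` forces it down at high speed, `sprint` is a short
#' supra-threshold burst.
#'
#' Measurement noise is a smooth low-frequency Gaussian wander (two
#' random-phase sinusoids, periods 600 and 900 s, total SD `hr_noise_sd`),
#' reflecting the heavy on-device filtering of wrist-derived heart rate;
#' `hr_jitter_sd` adds optional white per-sample jitter for stress tests.
#'
#' @param profile a [participant_profile()] with known `true_vo2max`.
#' @param scenario an [swt_scenario()].
#' @param seed integer seed; the same profile + scenario + seed reproduce the
#'   session bit for bit.
#' @param hr_noise_sd SD of the smooth heart-rate wander, bpm (default 1).
#' @param speed_noise_sd SD of the smooth speed wander, km/h (default 0.05).
#' @param hr_jitter_sd SD of white per-sample heart-rate jitter, bpm
#'   (default 0).
#' @param lag_tau heart-rate onset time constant, s (default 30).
#' @return a [run_session()]; attribute `"scenario"` keeps the phase table.
#' @examples
#' p <- participant_profile("p1", 35, "female", 165, 60, hr_rest = 68,
#'                          true_vo2max = 35)
#' s <- simulate_run_session(p, scenario_clean_ramp(), seed = 7)
#' @export
simulate_run_session <- function(profile, scenario, seed,
                                 hr_noise_sd = 1, speed_noise_sd = 0.05,
                                 hr_jitter_sd = 0, lag_tau = 30) {
  stopifnot(inherits(profile, "participant_profile"),
            inherits(scenario, "swt_scenario"))
  if (is.na(profile$true_vo2max))
    abort("simulate_run_session needs a profile with known true_vo2max")
  v <- profile$true_vo2max
  A <- profile$hr_rest
  B <- profile$hr_max - profile$hr_rest
  n <- sum(scenario$duration_s)
  speed <- numeric(n)
  mode <- character(n)   # "lag" or "forced"
  hr_forced <- rep(NA_real_, n)

  with_seed(seed, {
    # first pass: speed trace and forced-HR markers
    pos <- 0L
    last_speed <- 0
    for (k in seq_len(nrow(scenario))) {
      ph <- scenario[k, ]
      idx <- pos + seq_len(ph$duration_s)
      sp <- switch(ph$phase,
        steady = rep(ph$from * v / 3.5, ph$duration_s),
        ramp = seq(ph$from, ph$to, length.out = ph$duration_s) * v / 3.5,
        stop = rep(0, ph$duration_s),
        stop_hr_rise = rep(0, ph$duration_s),
        downhill = rep(max(6.5, 1.25 * last_speed), ph$duration_s),
        sprint = rep(1.05 * v / 3.5, ph$duration_s),
        abort("unknown phase type '%s'", ph$phase))
      speed[idx] <- sp
      mode[idx] <- if (ph$phase %in% c("stop_hr_rise", "downhill", "sprint"))
        "forced" else "lag"
      pos <- pos + ph$duration_s
      if (ph$phase %in% c("stop", "stop_hr_rise")) last_speed <- last_speed
      else last_speed <- sp[length(sp)]
    }

    # second pass: heart-rate dynamics
    hr <- numeric(n)
    alpha <- 1 - exp(-1 / lag_tau)
    state <- A
    pos <- 0L
    for (k in seq_len(nrow(scenario))) {
      ph <- scenario[k, ]
      start_hr <- state
      for (j in seq_len(ph$duration_s)) {
        i <- pos + j
        if (ph$phase == "stop_hr_rise") {
          state <- start_hr + ph$param * j / ph$duration_s
        } else if (ph$phase == "downhill") {
          state <- max(A, start_hr - ph$param * j / ph$duration_s)
        } else if (ph$phase == "sprint") {
          state <- min(profile$hr_max, start_hr + 1.5 * j)
        } else {
          target <- A + B * min(1, 3.5 * speed[i] / v)
          state <- state + alpha * (target - state)
        }
        hr[i] <- state
      }
      pos <- pos + ph$duration_s
    }

    # smooth measurement wander + optional white jitter
    t <- seq_len(n) - 1
    wander <- function(sd_total, p1, p2) {
      # two random-phase sinusoids, amplitude sd_total each, so the summed
      # process has variance 2 * sd_total^2 / 2 = sd_total^2
      sd_total * (sin(2 * pi * t / p1 + runif(1, 0, 2 * pi)) +
                  sin(2 * pi * t / p2 + runif(1, 0, 2 * pi)))
    }
    hr <- hr + wander(hr_noise_sd, 600, 900)
    if (hr_jitter_sd > 0) hr <- hr + rnorm(n, 0, hr_jitter_sd)
    moving <- speed > 0
    sp_noise <- wander(speed_noise_sd, 240, 350)
    speed[moving] <- pmax(0, speed[moving] + sp_noise[moving])

    hr <- pmin(230, pmax(30, hr))
    ses <- run_session(t, hr, speed, profile)
    attr(ses, "scenario") <- scenario
    ses
  })
}
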