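# CSV exchange formats. Dialect: comma separator, "." decimal, UTF-8,
# mandatory header, booleans written as 0/1.

SESSION_COLS <- c("t_s", "hr_bpm", "speed_kmh")

COHORT_COLS <- c("id", "age", "sex", "height", "weight", "bmi", "hr_rest",
                 "hr_max", "spo2", "sbp", "dbp", "smoker", "drinker", "rbc",
                 "hgb", "hct", "mcv", "mch", "mchc", "rdw_cv", "rdw_sd",
                 "vo2max_cpet", "vo2max_swt", "lls_headache", "lls_gi",
                 "lls_fatigue", "lls_dizziness", "ams")

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    abort("%s is missing required column(s): %s", what,
          paste(missing, collapse = ", "))
}

#' Read and write run-session CSV files
#'
#' Sessions are exchanged as CSV with columns `t_s, hr_bpm, speed_kmh`
#' (header required, 1 Hz, "." decimal, UTF-8). A non-uniform time grid is
#' resampled to 1 Hz by linear interpolation with a warning.
#'
#' @param path file path.
#' @param profile a [participant_profile()] to attach; required because the
#'   estimator needs age/HRmax, which the session file does not carry.
#' @return `read_session_csv()` returns a [run_session()];
#'   `write_session_csv()` returns `path` invisibly.
#' @export
read_session_csv <- function(path, profile) {
  if (!file.exists(path)) abort("no such file: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) abort("empty session file: %s", path)
  check_columns(df, SESSION_COLS, "session file")
  for (col in SESSION_COLS) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      abort("non-numeric value in column '%s' at data row(s) %s", col,
            paste(head(bad, 5), collapse = ", "))
    }
  }
  if (any(diff(df$t_s) <= 0)) {
    bad <- which(diff(df$t_s) <= 0)[1]
    abort("time must be strictly increasing (violated at data row %d)",
          bad + 1)
  }
  dt <- diff(df$t_s)
  if (max(abs(dt - 1)) > 1e-9) {
    warning("non-uniform or non-1 Hz time grid: resampling to 1 Hz")
    grid <- seq(min(df$t_s), max(df$t_s), by = 1)
    df <- data.frame(t_s = grid,
                     hr_bpm = approx(df$t_s, df$hr_bpm, grid)$y,
                     speed_kmh = approx(df$t_s, df$speed_kmh, grid)$y)
  }
  run_session(df$t_s, df$hr_bpm, df$speed_kmh, profile)
}

#' @rdname read_session_csv
#' @param session a [run_session()] to write.
#' @export
write_session_csv <- function(session, path) {
  stopifnot(inherits(session, "run_session"))
  write.csv(as.data.frame(session), path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write cohort CSV files
#'
#' One row per participant with every cohort column (see
#' [simulate_cohort()]); booleans are stored as 0/1. On reading, each row is
#' validated, including the AMS/Lake-Louise consistency rule (`ams` must
#' equal `headache >= 1 AND total >= 3`); a violating row is rejected with
#' its participant id.
#'
#' @param path file path.
#' @return `read_cohort_csv()` returns a cohort `data.frame` of class
#'   `swt_cohort`; `write_cohort_csv()` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) abort("no such file: %s", path)
  info <- file.info(path)
  if (is.na(info$size) || info$size == 0) abort("empty cohort file: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) abort("cohort file has a header but no rows: %s", path)
  check_columns(df, COHORT_COLS, "cohort file")
  for (col in c("smoker", "drinker", "ams")) df[[col]] <- df[[col]] != 0
  lls <- df[, c("lls_headache", "lls_gi", "lls_fatigue", "lls_dizziness")]
  if (!all(as.matrix(lls) %in% 0:3))
    abort("Lake Louise items must be integers in 0..3")
  expected <- ams_from_lls(df$lls_headache, df$lls_gi, df$lls_fatigue,
                           df$lls_dizziness)
  bad <- which(df$ams != expected)
  if (length(bad))
    abort("AMS label inconsistent with Lake Louise items for participant(s): %s",
          paste(df$id[bad], collapse = ", "))
  class(df) <- c("swt_cohort", "data.frame")
  df
}

#' @rdname read_cohort_csv
#' @param cohort a cohort `data.frame`.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  out <- as.data.frame(cohort)
  for (col in c("smoker", "drinker", "ams"))
    if (col %in% names(out)) out[[col]] <- as.integer(out[[col]])
  write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Pipeline configuration
#'
#' Everything a full reproducible run needs: the estimator thresholds, the
#' cohort generative parameters, the number of demonstration run sessions,
#' and the master seed. Round-trips losslessly through a YAML file; unknown
#' keys in a file are rejected.
#'
#' @param seed master seed for the run.
#' @param n_sessions number of demonstration run sessions simulated and
#'   estimated end to end.
#' @param swt an [swt_config()].
#' @param cohort a [cohort_config()]; its seed is derived from `seed`.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_sessions = 5, swt = swt_config(),
                            cohort = cohort_config(seed = seed)) {
  stopifnot(inherits(swt, "swt_config"), inherits(cohort, "cohort_config"))
  structure(list(seed = as.integer(seed), n_sessions = as.integer(n_sessions),
                 swt = swt, cohort = cohort),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config` to write.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- list(seed = config$seed, n_sessions = config$n_sessions,
            swt = unclass(config$swt), cohort = unclass(config$cohort))
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort("no such file: %s", path)
  x <- yaml::read_yaml(path)
  known <- c("seed", "n_sessions", "swt", "cohort")
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    abort("unknown config key(s): %s", paste(unknown, collapse = ", "))
  swt_args <- x$swt %||% list()
  bad <- setdiff(names(swt_args), names(formals(swt_config)))
  if (length(bad))
    abort("unknown swt config key(s): %s", paste(bad, collapse = ", "))
  coh_args <- x$cohort %||% list()
  bad <- setdiff(names(coh_args), names(formals(cohort_config)))
  if (length(bad))
    abort("unknown cohort config key(s): %s", paste(bad, collapse = ", "))
  pipeline_config(seed = x$seed %||% 1,
                  n_sessions = x$n_sessions %||% 5,
                  swt = do.call(swt_config, swt_args),
                  cohort = do.call(cohort_config, coh_args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
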