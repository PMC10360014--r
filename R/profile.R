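#' Participant profile
#'
#' Bundles the anthropometric and cardiovascular quantities the estimator
#' needs: age, sex, height, weight, resting and maximum heart rate, and the
#' (known or assumed) true VO2max used when simulating runs.
#'
#' @param id participant identifier (coerced to character).
#' @param age age in years, in \[18, 80\].
#' @param sex `"female"` or `"male"`.
#' @param height height in cm.
#' @param weight weight in kg.
#' @param hr_rest resting heart rate, bpm.
#' @param hr_max maximum heart rate, bpm, in \[120, 220\]. Defaults to the
#'   conventional `220 - age` when not supplied.
#' @param true_vo2max true maximum oxygen consumption in mL·kg^-1·min^-1,
#'   in \[15, 80\]. Used by the run simulator; may be `NA` for real data.
#' @return an object of class `participant_profile`: a list with the fields
#'   above plus `bmi` (kg/m^2, consistent with height/weight to 0.1).
#' @examples
#' participant_profile("p1", age = 35, sex = "female", height = 165,
#'                     weight = 60, hr_rest = 68, true_vo2max = 38)
#' @export
participant_profile <- function(id, age, sex = c("female", "male"), height,
                                weight, hr_rest, hr_max = NULL,
                                true_vo2max = NA_real_) {
  sex <- match.arg(sex)
  stopifnot(is_scalar_num(age), is_scalar_num(height), is_scalar_num(weight),
            is_scalar_num(hr_rest))
  if (age < 18 || age > 80) abort("age must be in [18, 80], got %s", age)
  if (is.null(hr_max)) hr_max <- 220 - age
  stopifnot(is_scalar_num(hr_max))
  if (hr_max < 120 || hr_max > 220)
    abort("hr_max must be in [120, 220], got %s", hr_max)
  if (hr_rest >= hr_max)
    abort("hr_rest (%s) must be below hr_max (%s)", hr_rest, hr_max)
  if (!is.na(true_vo2max) && (true_vo2max < 15 || true_vo2max > 80))
    abort("true_vo2max must be in [15, 80], got %s", true_vo2max)
  bmi <- round(weight / (height / 100)^2, 1)
  structure(list(id = as.character(id), age = age, sex = sex,
                 height = height, weight = weight, bmi = bmi,
                 hr_rest = hr_rest, hr_max = hr_max,
                 true_vo2max = true_vo2max),
            class = "participant_profile")
}

#' @export
print.participant_profile <- function(x, ...) {
  cat(sprintf("Participant %s: %s, %g y, %g cm, %g kg (BMI %g)\n",
              x$id, x$sex, x$age, x$height, x$weight, x$bmi))
  cat(sprintf("  HR rest/max: %g/%g bpm; true VO2max: %s mL/kg/min\n",
              x$hr_rest, x$hr_max,
              if (is.na(x$true_vo2max)) "unknown" else format(x$true_vo2max)))
  invisible(x)
}

#' Extract participant profiles from a simulated cohort
#'
#' Converts cohort rows into [participant_profile()] objects, taking the
#' reference (CPET) VO2max as the true value, so run sessions can be
#' simulated for cohort members.
#'
#' @param cohort a cohort `data.frame` as produced by [simulate_cohort()].
#' @return a list of `participant_profile` objects.
#' @export
cohort_profiles <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  lapply(seq_len(nrow(cohort)), function(i) {
    r <- cohort[i, ]
    participant_profile(r$id, age = r$age, sex = as.character(r$sex),
                        height = r$height, weight = r$weight,
                        hr_rest = r$hr_rest, hr_max = r$hr_max,
                        true_vo2max = r$vo2max_cpet)
  })
}
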