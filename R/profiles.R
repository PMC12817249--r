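#' Construct a synthetic subject profile
#'
#' A subject profile bundles the demographics and physiological set-points
#' that drive the biomarker simulators: the circadian cortisol parameters
#' (acrophase, amplitude, basal level), basal glucose, skin temperature and
#' heart rate, schedule type and lifestyle habits. Defaults describe a
#' healthy adult on a regular day/night schedule.
#'
#' Subjects on an inverted schedule have their cortisol acrophase shifted by
#' exactly 12 h relative to the normal-schedule default, reflecting that the
#' circadian pattern follows schedule behaviour rather than clock time. A
#' habitual coffee intake elevates the simulated sweat cortisol curve by a
#' multiplicative uplift; an exercise habit lowers basal heart rate by a
#' fixed offset. The default acrophase is a configuration choice (08:00),
#' not a physiological claim.
#'
#' @param subject_id Subject identifier string.
#' @param group Cohort label: one of `"ND"`, `"DR"`, `"MD"`, `"SD"`,
#'   `"healthy"`, `"patient"`.
#' @param schedule `"normal"` or `"inverted"` daily schedule.
#' @param exercise_habit,coffee_habit Logical lifestyle flags.
#' @param gender `"female"` or `"male"` (encoded numerically downstream).
#' @param age Age in years.
#' @param height Height in cm.
#' @param weight Weight in kg.
#' @param mean_bp Mean blood pressure in mmHg.
#' @param acrophase Clock time (decimal hours in `[0, 24)`) of the cortisol
#'   peak for a normal schedule; an inverted schedule shifts it by 12 h.
#' @param amplitude_cortisol Peak-minus-basal cortisol amplitude in nM.
#' @param basal_cortisol Basal (trough-side) cortisol in nM.
#' @param basal_glucose Basal sweat glucose in uM.
#' @param basal_st Basal skin temperature in degrees C.
#' @param basal_hr Basal heart rate in bpm.
#' @param exercise_hr_offset Reduction of basal HR (bpm) when
#'   `exercise_habit` is `TRUE`.
#' @param coffee_cortisol_uplift Multiplicative factor applied to the whole
#'   cortisol day curve when `coffee_habit` is `TRUE`.
#' @return A `stressci_profile` object (a named list).
#' @export
#' @examples
#' p <- subject_profile("S01", coffee_habit = TRUE)
#' p$acrophase
subject_profile <- function(subject_id = "S01",
                            group = c("healthy", "patient", "ND", "DR", "MD", "SD"),
                            schedule = c("normal", "inverted"),
                            exercise_habit = FALSE,
                            coffee_habit = FALSE,
                            gender = c("female", "male"),
                            age = 30,
                            height = 170,
                            weight = 65,
                            mean_bp = 90,
                            acrophase = 8,
                            amplitude_cortisol = 120,
                            basal_cortisol = 80,
                            basal_glucose = 60,
                            basal_st = 33.5,
                            basal_hr = 72,
                            exercise_hr_offset = 8,
                            coffee_cortisol_uplift = 1.25) {
  group <- match.arg(group)
  schedule <- match.arg(schedule)
  gender <- match.arg(gender)
  check_number(age, "age", min = 1e-9)
  check_number(height, "height", min = 1e-9)
  check_number(weight, "weight", min = 1e-9)
  check_number(mean_bp, "mean_bp", min = 1e-9)
  check_number(acrophase, "acrophase", min = 0)
  if (acrophase >= 24) {
    abort("`acrophase` must be in [0, 24).", class = "stressci_invalid_parameter")
  }
  check_number(amplitude_cortisol, "amplitude_cortisol", min = 0)
  check_number(basal_cortisol, "basal_cortisol", min = 1e-9)
  check_number(basal_glucose, "basal_glucose", min = 1e-9)
  check_number(basal_st, "basal_st", min = 1e-9)
  check_number(basal_hr, "basal_hr", min = 1e-9)
  check_number(exercise_hr_offset, "exercise_hr_offset", min = 0)
  check_number(coffee_cortisol_uplift, "coffee_cortisol_uplift", min = 1e-9)

  if (schedule == "inverted") {
    acrophase <- (acrophase + 12) %% 24
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      group = group, schedule = schedule,
      exercise_habit = isTRUE(exercise_habit),
      coffee_habit = isTRUE(coffee_habit),
      gender = gender, age = age, height = height, weight = weight,
      mean_bp = mean_bp, acrophase = acrophase,
      amplitude_cortisol = amplitude_cortisol,
      basal_cortisol = basal_cortisol, basal_glucose = basal_glucose,
      basal_st = basal_st, basal_hr = basal_hr,
      exercise_hr_offset = exercise_hr_offset,
      coffee_cortisol_uplift = coffee_cortisol_uplift
    ),
    class = "stressci_profile"
  )
}

#' @export
print.stressci_profile <- function(x, ...) {
  cat(sprintf(
    "<stressci_profile> %s  group=%s  schedule=%s  acrophase=%.2f h\n",
    x$subject_id, x$group, x$schedule, x$acrophase
  ))
  cat(sprintf(
    "  basal: cortisol %.0f nM (amp %.0f), glucose %.0f uM, ST %.1f C, HR %.0f bpm\n",
    x$basal_cortisol, x$amplitude_cortisol, x$basal_glucose, x$basal_st, x$basal_hr
  ))
  invisible(x)
}

#' Construct a stress event for simulation
#'
#' A stress event perturbs the biomarker panel multiplicatively: each series
#' is scaled by `1 + intensity * gain[b] * kernel(t - onset - lag[b])`, where
#' the kernel rises smoothly over the event duration to a unit peak and then
#' decays exponentially with the configured half-life. The glucose response
#' lags the cortisol response by default, matching the delayed glycaemic
#' reaction observed during acute stress testing.
#'
#' @param onset Event onset in clock-hours.
#' @param duration Stressor duration in minutes (rise time of the kernel).
#' @param intensity Dimensionless event intensity (`0` means no effect).
#' @param gain Named numeric vector of per-biomarker relative amplitudes
#'   (names among `cortisol`, `glucose`, `st`, `hr`).
#' @param lag Named numeric vector of per-biomarker lags in minutes.
#' @param decay_halflife Post-peak exponential half-life in minutes.
#' @return A `stressci_event` object.
#' @export
#' @examples
#' stress_event(onset = 10, duration = 15, intensity = 1)
stress_event <- function(onset = 12,
                         duration = 15,
                         intensity = 1,
                         gain = c(cortisol = 0.6, glucose = 0.25, st = 0.02, hr = 0.2),
                         lag = c(cortisol = 5, glucose = 20, st = 2, hr = 0),
                         decay_halflife = 20) {
  check_number(onset, "onset", min = 0)
  check_number(duration, "duration", min = 1e-9)
  check_number(intensity, "intensity", min = 0)
  check_number(decay_halflife, "decay_halflife", min = 1e-9)
  known <- c("cortisol", "glucose", "st", "hr")
  if (is.null(names(gain)) || !all(names(gain) %in% known)) {
    abort("`gain` must be named with biomarker keys.", class = "stressci_key_error")
  }
  if (is.null(names(lag)) || !all(names(lag) %in% known)) {
    abort("`lag` must be named with biomarker keys.", class = "stressci_key_error")
  }
  structure(
    list(
      onset = onset, duration = duration, intensity = intensity,
      gain = gain, lag = lag, decay_halflife = decay_halflife
    ),
    class = "stressci_event"
  )
}
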