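# Periodic single-peak day-curve shape with optional skew: a von-Mises-style
# bump exp(kappa * (cos(theta') - 1)) with the phase warped by
# theta' = theta + skew * sin(theta). The warp is monotone for |skew| < 1,
# keeps the peak (value 1) exactly at theta = 0, preserves 24 h periodicity,
# and puts the trough half a period away.
day_curve_shape <- function(t, acrophase, kappa = 2, skew = 0) {
  theta <- 2 * pi * (t - acrophase) / 24
  theta_w <- theta + skew * sin(theta)
  exp(kappa * (cos(theta_w) - 1))
}

#' Simulate a diurnal sweat-cortisol series
#'
#' Generates cortisol following a single-peak circadian day curve: a skewed
#' cosinor-family bump peaking at the profile's acrophase (trough 12 h
#' away), riding on the basal level, plus zero-truncated Gaussian noise so
#' the series stays strictly positive. A habitual coffee intake scales the
#' whole curve by the profile's configured uplift, reflecting the elevated
#' sweat cortisol observed in habitual coffee drinkers.
#'
#' @param profile A [subject_profile()].
#' @param times Clock-hours in `[0, 24)` at which to evaluate.
#' @param noise_sd Noise standard deviation in nM (>= 0).
#' @param seed Integer seed (or `NULL`).
#' @param kappa Concentration of the circadian bump (larger = narrower peak).
#' @param skew Phase-warp skew in `(-1, 1)`; `0` gives a plain cosinor bump.
#' @return A tibble with columns `time` and `cortisol` (nM).
#' @export
#' @examples
#' p <- subject_profile()
#' simulate_cortisol_diurnal(p, times = c(8, 12, 16, 20), noise_sd = 0)
simulate_cortisol_diurnal <- function(profile, times, noise_sd = 5, seed = NULL,
                                      kappa = 2, skew = 0.3) {
  stopifnot(inherits(profile, "stressci_profile"))
  check_clock_hours(times, "times")
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(kappa, "kappa", min = 1e-9)
  check_number(skew, "skew", min = -0.99, max = 0.99)

  mu <- profile$basal_cortisol +
    profile$amplitude_cortisol * day_curve_shape(times, profile$acrophase, kappa, skew)
  if (profile$coffee_habit) {
    mu <- mu * profile$coffee_cortisol_uplift
  }
  values <- with_seed_or_current(seed, rnorm_pos(mu, noise_sd))
  tibble(time = times, cortisol = values)
}

# Post-meal glucose excursion: gamma-shaped unit-peak pulse
# h(tau) = (tau/rise) * exp(1 - tau/rise) for tau > 0, peaking exactly
# `rise` hours after the meal and decaying exponentially thereafter.
meal_pulse_kernel <- function(tau, rise) {
  out <- numeric(length(tau))
  pos <- tau > 0
  out[pos] <- (tau[pos] / rise) * exp(1 - tau[pos] / rise)
  out
}

#' Simulate a meal-pulsed sweat-glucose series
#'
#' Glucose is modelled as a basal level plus one lagged rise-and-decay pulse
#' per meal (unit-peak gamma kernel scaled by `meal_amplitude`, peaking
#' `pulse_rise` hours after the meal) plus zero-truncated Gaussian noise.
#'
#' @inheritParams simulate_cortisol_diurnal
#' @param meal_times Clock-hours of meals (default 08:00, 12:30, 18:30).
#' @param meal_amplitude Peak excursion per meal in uM (>= 0).
#' @param pulse_rise Time from meal to pulse peak, hours.
#' @param noise_sd Noise standard deviation in uM.
#' @return A tibble with columns `time` and `glucose` (uM).
#' @export
#' @examples
#' p <- subject_profile()
#' simulate_glucose(p, times = seq(8, 22, by = 2), noise_sd = 0)
simulate_glucose <- function(profile, times, meal_times = c(8, 12.5, 18.5),
                             meal_amplitude = 40, noise_sd = 3, seed = NULL,
                             pulse_rise = 0.75) {
  stopifnot(inherits(profile, "stressci_profile"))
  check_clock_hours(times, "times")
  if (length(meal_times)) check_clock_hours(meal_times, "meal_times")
  if (!is.numeric(meal_amplitude) || meal_amplitude < 0) {
    abort("`meal_amplitude` must be >= 0.", class = "stressci_invalid_parameter")
  }
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(pulse_rise, "pulse_rise", min = 1e-9)

  mu <- rep(profile$basal_glucose, length(times))
  for (m in meal_times) {
    mu <- mu + meal_amplitude * meal_pulse_kernel(times - m, pulse_rise)
  }
  values <- with_seed_or_current(seed, rnorm_pos(mu, noise_sd))
  tibble(time = times, glucose = values)
}

#' Simulate skin-temperature and heart-rate series
#'
#' ST and HR are stationary around the profile's basal values (no circadian
#' structure is imposed, matching their relatively flat day patterns). An
#' exercise habit lowers basal HR by the profile's configured offset.
#'
#' @inheritParams simulate_cortisol_diurnal
#' @param noise_sd_st Noise sd for skin temperature, degrees C.
#' @param noise_sd_hr Noise sd for heart rate, bpm.
#' @return A tibble with columns `time`, `st` (C) and `hr` (bpm).
#' @export
simulate_st_hr <- function(profile, times, noise_sd_st = 0.15, noise_sd_hr = 3,
                           seed = NULL) {
  stopifnot(inherits(profile, "stressci_profile"))
  check_clock_hours(times, "times")
  check_number(noise_sd_st, "noise_sd_st", min = 0)
  check_number(noise_sd_hr, "noise_sd_hr", min = 0)

  hr_base <- profile$basal_hr - if (profile$exercise_habit) profile$exercise_hr_offset else 0
  vals <- with_seed_or_current(seed, {
    st <- rnorm_pos(rep(profile$basal_st, length(times)), noise_sd_st)
    hr <- rnorm_pos(rep(hr_base, length(times)), noise_sd_hr)
    list(st = st, hr = hr)
  })
  tibble(time = times, st = vals$st, hr = vals$hr)
}

#' Simulate a full biomarker panel for one subject
#'
#' Convenience wrapper producing one [tibble][tibble::tibble] of panel
#' records (`subject_id`, `time`, `cortisol`, `glucose`, `st`, `hr`) by
#' running the three per-biomarker simulators with sub-seeds derived from
#' `seed`.
#'
#' @inheritParams simulate_cortisol_diurnal
#' @param noise Named list of noise sds: `cortisol` (nM), `glucose` (uM),
#'   `st` (C), `hr` (bpm).
#' @param meal_times,meal_amplitude Passed to [simulate_glucose()].
#' @return A panel tibble, one row per time point.
#' @export
#' @examples
#' simulate_panel(subject_profile(), times = c(8, 14, 20), seed = 1)
simulate_panel <- function(profile, times,
                           noise = list(cortisol = 5, glucose = 3, st = 0.15, hr = 3),
                           meal_times = c(8, 12.5, 18.5), meal_amplitude = 40,
                           seed = NULL) {
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL) else as.list(seed + 0:2)
  cort <- simulate_cortisol_diurnal(profile, times, noise$cortisol, seed = seeds[[1]])
  gluc <- simulate_glucose(profile, times, meal_times, meal_amplitude,
    noise$glucose,
    seed = seeds[[2]]
  )
  sthr <- simulate_st_hr(profile, times, noise$st, noise$hr, seed = seeds[[3]])
  tibble(
    subject_id = profile$subject_id, time = times,
    cortisol = cort$cortisol, glucose = gluc$glucose,
    st = sthr$st, hr = sthr$hr
  )
}

# Stress-response kernel, unit peak: smooth half-cosine rise over the event
# duration, then exponential decay with the configured half-life. Exactly
# zero for tau <= 0, so values before onset + lag are untouched.
stress_kernel <- function(tau_min, duration_min, halflife_min) {
  out <- numeric(length(tau_min))
  rise <- tau_min > 0 & tau_min <= duration_min
  out[rise] <- 0.5 * (1 - cos(pi * tau_min[rise] / duration_min))
  post <- tau_min > duration_min
  out[post] <- exp(-log(2) * (tau_min[post] - duration_min) / halflife_min)
  out
}

#' Inject an acute-stress response into a biomarker panel
#'
#' Each biomarker series is multiplied by
#' `1 + intensity * gain[b] * kernel(t - onset - lag[b])`, with a
#' rise-and-decay kernel of unit peak (half-cosine rise over the event
#' duration, then exponential decay). Pre-event values (before
#' `onset + lag`) are conserved exactly, and the series returns towards
#' baseline several half-lives after `onset + duration`. Biomarker-specific
#' lags reproduce the delayed glucose response relative to cortisol.
#'
#' @param panel A panel tibble with a `time` column (clock-hours) and one
#'   column per biomarker to perturb.
#' @param event A [stress_event()].
#' @return The panel with perturbed biomarker columns.
#' @export
#' @examples
#' panel <- simulate_panel(subject_profile(), times = seq(8, 22, by = 0.25), seed = 1)
#' stressed <- inject_stress_response(panel, stress_event(onset = 12))
inject_stress_response <- function(panel, event) {
  stopifnot(inherits(event, "stressci_event"))
  if (!"time" %in% names(panel)) {
    abort("`panel` must have a `time` column.", class = "stressci_schema_error")
  }
  if (event$onset < min(panel$time) || event$onset > max(panel$time)) {
    abort("Event onset must fall within the panel time span.", class = "stressci_invalid_parameter")
  }
  missing_keys <- setdiff(names(event$gain), names(panel))
  if (length(missing_keys)) {
    abort(
      sprintf("Biomarker(s) %s in `gain` not present in panel.", toString(missing_keys)),
      class = "stressci_key_error"
    )
  }
  out <- panel
  for (b in names(event$gain)) {
    lag_min <- if (b %in% names(event$lag)) event$lag[[b]] else 0
    tau_min <- (panel$time - event$onset) * 60 - lag_min
    k <- stress_kernel(tau_min, event$duration, event$decay_halflife)
    out[[b]] <- panel[[b]] * (1 + event$intensity * event$gain[[b]] * k)
  }
  out
}
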