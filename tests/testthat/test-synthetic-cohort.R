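test_that("noiseless cortisol peaks at the configured acrophase and is periodic", {
  grid <- seq(0, 24 - 1 / 60, by = 1 / 60)
  for (acro in c(8, 14, 20)) {
    p <- subject_profile(acrophase = acro)
    s <- simulate_cortisol_diurnal(p, grid, noise_sd = 0)
    expect_lt(abs(s$cortisol[which.max(s$cortisol)] - max(s$cortisol)), 1e-12)
    expect_lt(abs(grid[which.max(s$cortisol)] - acro), 1 / 60 + 1e-9)
    # peak value is basal + amplitude, trough half a period away
    expect_equal(max(s$cortisol), p$basal_cortisol + p$amplitude_cortisol, tolerance = 1e-6)
  }
  # 24 h periodicity of the noiseless curve
  p <- subject_profile(acrophase = 14)
  t0 <- c(1, 5.5, 13, 20)
  a <- simulate_cortisol_diurnal(p, t0, noise_sd = 0)$cortisol
  b <- simulate_cortisol_diurnal(p, (t0 + 24) %% 24, noise_sd = 0)$cortisol
  expect_equal(a, b)
})

test_that("inverted schedule is an exact 12 h circular shift; amplitude 0 is constant", {
  times <- seq(0, 23.75, by = 0.25)
  norm <- simulate_cortisol_diurnal(subject_profile(), (times - 12) %% 24, noise_sd = 0)
  inv <- simulate_cortisol_diurnal(subject_profile(schedule = "inverted"), times, noise_sd = 0)
  expect_equal(inv$cortisol, norm$cortisol, tolerance = 1e-12)

  flat <- simulate_cortisol_diurnal(subject_profile(amplitude_cortisol = 0), times, noise_sd = 0)
  expect_equal(flat$cortisol, rep(80, length(times)))
})

test_that("coffee habit uplifts cortisol only; exercise habit lowers HR by the offset", {
  times <- seq(8, 22, by = 1)
  base <- subject_profile()
  coffee <- subject_profile(coffee_habit = TRUE)
  c0 <- simulate_cortisol_diurnal(base, times, noise_sd = 0)$cortisol
  c1 <- simulate_cortisol_diurnal(coffee, times, noise_sd = 0)$cortisol
  expect_equal(c1, c0 * base$coffee_cortisol_uplift)
  # ST/HR unaffected by coffee
  s0 <- simulate_st_hr(base, times, 0.1, 2, seed = 5)
  s1 <- simulate_st_hr(coffee, times, 0.1, 2, seed = 5)
  expect_identical(s0, s1)
  # exercise habit: same seed, mean HR difference equals the offset
  ex <- subject_profile(exercise_habit = TRUE)
  h0 <- simulate_st_hr(base, times, 0, 0)$hr
  h1 <- simulate_st_hr(ex, times, 0, 0)$hr
  expect_equal(mean(h0) - mean(h1), base$exercise_hr_offset)
})

test_that("glucose is basal without meals and pulses peak at meal + rise time", {
  p <- subject_profile()
  grid <- seq(0, 23.99, by = 1 / 60)
  none <- simulate_glucose(p, grid, meal_times = numeric(0), noise_sd = 0)
  expect_equal(none$glucose, rep(p$basal_glucose, length(grid)))

  one <- simulate_glucose(p, grid, meal_times = 12, noise_sd = 0, pulse_rise = 0.75)
  expect_equal(grid[which.max(one$glucose)], 12.75, tolerance = 1 / 60 + 1e-9)

  # two far-apart identical meals: peak values agree within 1%
  two <- simulate_glucose(p, grid, meal_times = c(9, 18), noise_sd = 0)
  pk1 <- max(two$glucose[grid < 13.5])
  pk2 <- max(two$glucose[grid >= 13.5])
  expect_lt(abs(pk1 - pk2) / pk1, 0.01)

  expect_error(
    simulate_glucose(p, grid, meal_amplitude = -1),
    class = "stressci_invalid_parameter"
  )
})

test_that("all generated biomarker series are strictly positive, finite, seed-deterministic", {
  p <- subject_profile()
  times <- seq(8, 22, by = 0.5)
  a <- simulate_panel(p, times, seed = 11)
  b <- simulate_panel(p, times, seed = 11)
  expect_identical(a, b)
  for (col in c("cortisol", "glucose", "st", "hr")) {
    expect_true(all(is.finite(a[[col]])))
    expect_true(all(a[[col]] > 0))
  }
  # large noise relative to the mean still cannot push values negative
  huge <- simulate_cortisol_diurnal(p, times, noise_sd = 500, seed = 3)
  expect_true(all(huge$cortisol > 0))
})

test_that("stress injection conserves pre-event values and orders peak lags", {
  p <- subject_profile(acrophase = 3) # quiet morning curve in the window
  times <- seq(8, 16, by = 1 / 60)
  panel <- simulate_panel(p, times,
    noise = list(cortisol = 0, glucose = 0, st = 0, hr = 0),
    meal_times = numeric(0)
  )
  ev <- stress_event(onset = 10, duration = 15, intensity = 1.5)
  out <- inject_stress_response(panel, ev)

  # exactly unchanged before onset + lag (cortisol lag 5 min)
  pre <- times < 10 + ev$lag[["cortisol"]] / 60
  expect_identical(out$cortisol[pre], panel$cortisol[pre])

  # relative deviation peaks separated by the lag difference
  peak_t <- function(b) times[which.max(out[[b]] / panel[[b]])]
  expect_equal(
    (peak_t("glucose") - peak_t("cortisol")) * 60,
    ev$lag[["glucose"]] - ev$lag[["cortisol"]],
    tolerance = 1.5
  )

  # returns toward baseline long after the event
  tail_idx <- which(times > 10 + 5)
  rel_dev <- out$cortisol[tail_idx] / panel$cortisol[tail_idx] - 1
  peak_dev <- max(out$cortisol / panel$cortisol - 1)
  expect_lt(max(rel_dev), 0.01 * peak_dev)

  # intensity 0 is the identity
  same <- inject_stress_response(panel, stress_event(onset = 10, intensity = 0))
  expect_equal(same, panel)

  bad <- stress_event(onset = 10)
  names(bad$gain)[1] <- "unknown"
  expect_error(inject_stress_response(panel, bad), class = "stressci_key_error")
})

test_that("pulse traces have the right beat count, spacing and SNR", {
  tr60 <- simulate_pulse_trace(60, duration = 30, snr_db = Inf)
  expect_equal(unique(round(diff(tr60$true_beat_times), 9)), 1.0)

  tr72 <- simulate_pulse_trace(72, duration = 30, snr_db = Inf)
  expect_true(abs(length(tr72$true_beat_times) - 36) <= 1)

  # empirical SNR within 5% of requested 10 dB
  clean <- simulate_pulse_trace(72, duration = 30, snr_db = Inf)
  noisy <- simulate_pulse_trace(72, duration = 30, snr_db = 10, seed = 4)
  noise <- noisy$values - clean$values
  ratio <- mean(clean$values^2) / mean(noise^2)
  expect_lt(abs(ratio - 10) / 10, 0.05)

  expect_error(simulate_pulse_trace(72, sample_rate = 20), class = "stressci_invalid_parameter")
  expect_error(simulate_pulse_trace(250), class = "stressci_invalid_parameter")
  expect_error(simulate_pulse_trace(60, duration = 5), class = "stressci_invalid_parameter")
})

test_that("scale scores are affine in latent stress, clipped, and anchor the cutpoints", {
  expect_equal(generate_scale_scores(0, "STAIS"), 20) # minimum anchor
  expect_equal(generate_scale_scores(0, "SCL90"), 90)
  # monotone in latent
  s <- generate_scale_scores(c(0.5, 1.0, 2.0), "STAIS")
  expect_true(all(diff(s) > 0))
  # latent 1 maps to the lower cutpoint, ~1.714 to the upper
  expect_equal(generate_scale_scores(1, "STAIS"), 34)
  expect_equal(generate_scale_scores(24 / 14, "STAIS"), 44)
  # clipping to the admissible range
  expect_equal(generate_scale_scores(100, "STAIS"), 80)
  expect_error(generate_scale_scores(-1, "STAIS"), class = "stressci_invalid_parameter")
})

test_that("default depression cohort matches the study design counts", {
  cohort <- generate_depression_cohort(seed = 2)
  expect_equal(nrow(cohort), 147)
  subjects <- dplyr::distinct(cohort, subject_id, group)
  expect_equal(nrow(subjects), 49)
  expect_equal(sum(subjects$group %in% c("MD", "SD")), 23) # patient side
  expect_equal(sum(subjects$group %in% c("ND", "DR")), 26) # healthy side
  expect_identical(generate_depression_cohort(seed = 2), cohort)
  # demographics present and subject-constant
  per_sub <- dplyr::n_distinct(dplyr::distinct(cohort, subject_id, age, height, weight)$subject_id)
  expect_equal(per_sub, 49)
  expect_error(
    generate_depression_cohort(cohort_design(group_counts = c(ND = 5)), seed = 1),
    class = "stressci_config_error"
  )
})
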