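#' Build a pipeline configuration
#'
#' Bundles the settings that tie the stages together: scenario, seed,
#' acute-stress cutpoints (34/44 on the STAI-S scale), warning fraction
#' (0.8), benchmark time (08:00), biomarker inclusion, candidate baseline
#' families and split parameters. A YAML or JSON file with these fields can
#' be loaded and passed through [run_pipeline()].
#'
#' @param scenario One of `"tsst"`, `"cpt"`, `"circadian"`, `"depression"`.
#' @param seed Integer seed for every stochastic stage.
#' @param cutpoints Acute-stress critical points, increasing.
#' @param warning_fraction Warning trigger fraction in `(0, 1]`.
#' @param benchmark_time Benchmark clock time for retro-adjustment.
#' @param include_st Include skin temperature in the weighted index?
#'   (Excluded for the cold-pressor scenario, where ST shows no response.)
#' @param candidate_families Baseline families compared by LOOCV.
#' @param test_subjects Held-out subjects for the depression split.
#' @return A `stressci_config` list.
#' @export
pipeline_config <- function(scenario = c("tsst", "cpt", "circadian", "depression"),
                            seed = 1,
                            cutpoints = c(34, 44),
                            warning_fraction = 0.8,
                            benchmark_time = 8,
                            include_st = NULL,
                            candidate_families = c("cosinor", "skewed_peak", "constant"),
                            test_subjects = 10) {
  scenario <- match.arg(scenario)
  if (length(cutpoints) != 2L || cutpoints[1] >= cutpoints[2]) {
    abort("`cutpoints` must be two increasing values.", class = "stressci_config_error")
  }
  check_number(warning_fraction, "warning_fraction", min = 1e-12, max = 1)
  check_number(benchmark_time, "benchmark_time", min = 0, max = 24)
  include_st <- include_st %||% (scenario != "cpt")
  structure(
    list(
      scenario = scenario, seed = as.integer(seed), cutpoints = cutpoints,
      warning_fraction = warning_fraction, benchmark_time = benchmark_time,
      include_st = include_st, candidate_families = candidate_families,
      test_subjects = test_subjects
    ),
    class = "stressci_config"
  )
}

#' Run a full simulate-fit-index-classify pipeline
#'
#' Executes the scenario named in the configuration on synthetic data and
#' writes the stage outputs plus a run manifest (configuration hash, seed,
#' package version, timings) to `out_dir`, so deterministic stages can be
#' re-run bit-exactly.
#'
#' * `circadian`: simulates normal- and inverted-schedule subjects across
#'   48 h and fits circadian baselines; writes panels and model JSON.
#' * `tsst`: simulates a stress event over a dense day grid, computes the
#'   unweighted index stream against the pre-test control, and locates the
#'   warning trigger at the configured fraction of the maximum.
#' * `cpt`: simulates an acute-stress cohort, fits impact weights of the
#'   included biomarkers (ST excluded by default here) against STAI-S, and
#'   classifies acute-stress states at the configured cutpoints.
#' * `depression`: generates the 147-record cohort, fits pooled baselines,
#'   splits by subject, trains the classifier suite and the regression
#'   index, and writes evaluation metrics.
#'
#' @param config A `stressci_config` from [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the result bundle (list); side effect: files in
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("stressci_run_")) {
  stopifnot(inherits(config, "stressci_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  result <- switch(config$scenario,
    circadian = run_scenario_circadian(config, out_dir),
    tsst = run_scenario_tsst(config, out_dir),
    cpt = run_scenario_cpt(config, out_dir),
    depression = run_scenario_depression(config, out_dir)
  )
  manifest <- list(
    scenario = config$scenario, seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("stressci")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(result)
}

run_scenario_circadian <- function(config, out_dir) {
  times <- seq(0, 47.75, by = 0.25) %% 24
  times48 <- seq(0, 47.75, by = 0.25)
  fits <- list()
  for (sched in c("normal", "inverted")) {
    p <- subject_profile(paste0("C_", sched), schedule = sched)
    cort <- simulate_cortisol_diurnal(p, times, noise_sd = 4, seed = config$seed)
    panel <- tibble(
      subject_id = p$subject_id, time = times48,
      cortisol = cort$cortisol
    )
    readr::write_csv(panel, file.path(out_dir, sprintf("circadian_%s.csv", sched)))
    day <- tibble(time = times[times >= 8 & times <= 22], value = cort$cortisol[times >= 8 & times <= 22])
    fits[[sched]] <- select_model_loocv(day[seq(1, nrow(day), by = 4), ],
      candidate_families = config$candidate_families, biomarker = "cortisol"
    )
    write_baseline_json(fits[[sched]], file.path(out_dir, sprintf("baseline_%s.json", sched)))
  }
  fits
}

run_scenario_tsst <- function(config, out_dir) {
  # Afternoon session (stress testing is scheduled around 16:00, away from
  # the morning cortisol decline); the control is the panel recorded 30 min
  # before the stressor starts.
  p <- subject_profile("TSST01")
  times <- seq(14, 18, by = 1 / 60)
  panel <- simulate_panel(p, times, seed = config$seed)
  event <- stress_event(onset = 15, duration = 30, intensity = 1)
  stressed <- inject_stress_response(panel, event)
  ctrl_idx <- which.min(abs(times - (event$onset - 0.5)))
  control <- unlist(stressed[ctrl_idx, c("cortisol", "glucose", "st", "hr")])
  ssci1 <- compute_ssci1(
    stressed[, c("cortisol", "glucose", "st", "hr")],
    control
  )
  trig <- warning_trigger(ssci1,
    reference_max = max(ssci1),
    fraction = config$warning_fraction, times = times
  )
  out <- dplyr::mutate(stressed, ssci1 = ssci1)
  readr::write_csv(out, file.path(out_dir, "tsst_panel.csv"))
  jsonlite::write_json(
    list(
      warning_fraction = config$warning_fraction, max_ssci1 = max(ssci1),
      trigger_time = trig$time, trigger_index = trig$index
    ),
    file.path(out_dir, "tsst_warning.json"),
    auto_unbox = TRUE, digits = NA
  )
  list(panel = out, trigger = trig)
}

# Simulates an acute-stress test cohort: per subject a latent stress level,
# biomarker deviations proportional to it (ST unresponsive), and a STAI-S
# score from the same latent level.
simulate_cpt_cohort <- function(n_subjects, seed,
                                true_weights = c(cortisol = 18, glucose = 9, hr = 7),
                                noise_sd = 2) {
  with_seed_or_current(seed, {
    latent <- runif(n_subjects, 0, 2.2)
    dev <- tibble(
      cortisol = 0.5 * latent + rnorm(n_subjects, 0, 0.05),
      glucose = 0.3 * latent + rnorm(n_subjects, 0, 0.05),
      st = rnorm(n_subjects, 0, 0.01),
      hr = 0.25 * latent + rnorm(n_subjects, 0, 0.04)
    )
    stais <- 20 + as.matrix(dev[names(true_weights)]) %*% true_weights +
      rnorm(n_subjects, 0, noise_sd)
    list(deviations = dev, stais = pmin(pmax(as.numeric(stais), 20), 80), latent = latent)
  })
}

run_scenario_cpt <- function(config, out_dir) {
  included <- c("cortisol", "glucose", if (config$include_st) "st", "hr")
  cohort <- simulate_cpt_cohort(24, config$seed)
  w <- estimate_weights_mlr(cohort$deviations[included], cohort$stais)
  write_weights_json(w, file.path(out_dir, "weights.json"))
  scores <- vapply(seq_len(nrow(cohort$deviations)), function(i) {
    compute_ssci2(cohort$deviations[i, ], w, with_intercept = TRUE)
  }, numeric(1))
  states <- classify_as_state(scores, config$cutpoints)
  truth <- classify_as_state(cohort$stais, config$cutpoints)
  out <- dplyr::mutate(cohort$deviations,
    stais = cohort$stais,
    ssci2 = scores, state = states, true_state = truth
  )
  readr::write_csv(out, file.path(out_dir, "cpt_scores.csv"))
  list(weights = w, scores = out, accuracy = mean(states == truth))
}

run_scenario_depression <- function(config, out_dir) {
  cohort <- generate_depression_cohort(seed = config$seed)
  readr::write_csv(cohort, file.path(out_dir, "cohort.csv"))
  models <- pretrain_baselines(seed = config$seed + 100)
  write_baseline_json(models$cortisol, file.path(out_dir, "baseline_cortisol.json"))
  write_baseline_json(models$glucose, file.path(out_dir, "baseline_glucose.json"))
  sp <- split_cohort(cohort, test_subjects = config$test_subjects, seed = config$seed)
  clf <- train_classifiers(sp$train, models, temporal = TRUE, seed = config$seed)
  ev <- evaluate_classifiers(clf, sp$test)
  reg <- regress_ssci3(sp$train, sp$test, models, temporal = TRUE)
  readr::write_csv(ev$summary, file.path(out_dir, "metrics.csv"))
  jsonlite::write_json(
    list(
      n_train = nrow(sp$train), n_test = nrow(sp$test),
      test_correlation = reg$test_correlation
    ),
    file.path(out_dir, "regression.json"),
    auto_unbox = TRUE, digits = NA
  )
  list(split = sp, classifiers = clf, evaluation = ev, regression = reg)
}

#' Pretrain population circadian baselines on synthetic volunteers
#'
#' Emulates baseline pretraining: simulates a dense day of cortisol and
#' glucose from the population profile, pools the volunteers, and selects
#' the per-biomarker model family by LOOCV (cortisol among rhythmic
#' families, glucose among meal-pulse/constant).
#'
#' @param n_volunteers Number of synthetic volunteers pooled.
#' @param n_times Sampling points per volunteer across the day window.
#' @param seed Integer seed.
#' @return Named list of `stressci_baseline` models (`cortisol`, `glucose`).
#' @export
pretrain_baselines <- function(n_volunteers = 11, n_times = 8, seed = 1) {
  p <- subject_profile("VOL")
  series <- with_seed_or_current(seed, {
    purrr::map_dfr(seq_len(n_volunteers), function(i) {
      times <- sort(runif(n_times, DAY_WINDOW[1], DAY_WINDOW[2]))
      cort <- simulate_cortisol_diurnal(p, times, noise_sd = 5)
      gluc <- simulate_glucose(p, times, noise_sd = 3)
      tibble(time = times, cortisol = cort$cortisol, glucose = gluc$glucose)
    })
  })
  list(
    cortisol = select_model_loocv(
      tibble(time = series$time, value = series$cortisol),
      candidate_families = c("skewed_peak", "cosinor", "constant"),
      biomarker = "cortisol"
    ),
    glucose = select_model_loocv(
      tibble(time = series$time, value = series$glucose),
      candidate_families = c("meal_pulse", "cosinor", "constant"),
      biomarker = "glucose"
    )
  )
}
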