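#' Default depression-cohort simulation design
#'
#' The default design emulates a clinical chronic-stress study: 49 subjects
#' (26 on the healthy side: non-depressed ND and depression-risk DR; 23 on
#' the patient side: mild MD and severe SD), each measured three times at
#' random clock times across the 08:00-22:00 day window, giving 147 panel
#' records with demographics and three psychometric scale scores (SCL-90,
#' SDS, SAS) plus STAI-S.
#'
#' Group severity acts through a latent chronic-stress level per group that
#' (i) scales cortisol, glucose and HR multiplicatively and shifts ST
#' slightly, and (ii) drives the scale scores through their affine maps.
#' `effect_scale = 0` removes all biomarker group effects (scale scores keep
#' their latent coupling), producing a null cohort for leakage checks.
#'
#' @param group_counts Named integer vector of subjects per group.
#' @param repeats Measurements per subject.
#' @param latent_by_group Named latent chronic-stress level per group.
#' @param effect_scale Global multiplier on the biomarker group effects.
#' @param gain Per-biomarker coupling of the latent level to the panel.
#' @param subject_sd Log-scale sd of between-subject multiplicative
#'   heterogeneity for cortisol/glucose/HR.
#' @param noise Named list of within-record measurement noise sds.
#' @param scale_noise_sd Noise sd (score units, pre-normalisation scale) on
#'   psychometric scores.
#' @return A design list for [generate_depression_cohort()].
#' @export
cohort_design <- function(group_counts = c(ND = 14, DR = 12, MD = 12, SD = 11),
                          repeats = 3,
                          latent_by_group = c(ND = 0.2, DR = 1.0, MD = 1.8, SD = 2.6),
                          effect_scale = 1,
                          gain = c(cortisol = 0.65, glucose = 0.35, st = 0.2, hr = 8),
                          subject_sd = 0.04,
                          noise = list(cortisol = 5, glucose = 3, st = 0.15, hr = 3),
                          scale_noise_sd = 2) {
  groups <- c("ND", "DR", "MD", "SD")
  if (!all(groups %in% names(group_counts))) {
    abort("`group_counts` must name all of ND, DR, MD, SD.", class = "stressci_config_error")
  }
  if (!all(groups %in% names(latent_by_group))) {
    abort("`latent_by_group` must cover every group.", class = "stressci_config_error")
  }
  list(
    group_counts = group_counts[groups], repeats = repeats,
    latent_by_group = latent_by_group[groups], effect_scale = effect_scale,
    gain = gain, subject_sd = subject_sd, noise = noise,
    scale_noise_sd = scale_noise_sd
  )
}

#' Generate a synthetic depression cohort
#'
#' Produces one row per (subject, repeat): the four-biomarker panel at a
#' random clock time in the day window, demographics (gender, age, height,
#' weight, mean blood pressure), the three chronic-stress scales (SCL-90,
#' SDS, SAS), a STAI-S score, the group label and the latent stress level
#' (simulation ground truth). Subject-level quantities are constant across
#' a subject's repeats. Deterministic given `design` and `seed`.
#'
#' Subjects share the population circadian cortisol shape and meal-pulsed
#' glucose shape, scaled per subject and per group, so that multiplicative
#' retro-adjustment to the benchmark time is exact up to measurement noise.
#'
#' @param design A [cohort_design()] list.
#' @param seed Integer seed.
#' @return A cohort tibble with `nrow = sum(group_counts) * repeats`.
#' @export
#' @examples
#' cohort <- generate_depression_cohort(seed = 1)
#' nrow(cohort) # 147
#' table(dplyr::distinct(cohort, subject_id, group)$group)
generate_depression_cohort <- function(design = cohort_design(), seed = 1) {
  groups <- rep(names(design$group_counts), times = design$group_counts)
  n_sub <- length(groups)
  ref <- subject_profile() # population set-points and circadian shape

  with_seed_or_current(seed, {
    subjects <- tibble(
      subject_id = sprintf("S%03d", seq_len(n_sub)),
      group = groups,
      latent0 = unname(design$latent_by_group[groups]),
      gender = sample(c("female", "male"), n_sub, replace = TRUE),
      age = round(runif(n_sub, 25, 70)),
      s_cortisol = exp(rnorm(n_sub, 0, design$subject_sd)),
      s_glucose = exp(rnorm(n_sub, 0, design$subject_sd)),
      s_hr = exp(rnorm(n_sub, 0, design$subject_sd / 2)),
      latent = pmax(latent0 + rnorm(n_sub, 0, 0.05), 0)
    )
    subjects$height <- round(ifelse(subjects$gender == "male",
      rnorm(n_sub, 175, 6), rnorm(n_sub, 162, 6)
    ), 1)
    subjects$weight <- round(pmax(rnorm(n_sub, 0.35 * subjects$height + 8, 6), 40), 1)
    subjects$mean_bp <- round(rnorm(n_sub, 90 + 2 * subjects$latent, 7), 1)

    es <- design$effect_scale
    rows <- purrr::map_dfr(seq_len(n_sub), function(i) {
      s <- subjects[i, ]
      times <- round(runif(design$repeats, DAY_WINDOW[1], DAY_WINDOW[2]), 2)
      mult <- function(g) 1 + es * design$gain[[g]] * s$latent
      cort_mu <- s$s_cortisol * mult("cortisol") *
        (ref$basal_cortisol + ref$amplitude_cortisol *
          day_curve_shape(times, ref$acrophase, kappa = 2, skew = 0.3))
      gluc_mu <- s$s_glucose * mult("glucose") *
        (ref$basal_glucose + 40 * (
          meal_pulse_kernel(times - 8, 0.75) +
            meal_pulse_kernel(times - 12.5, 0.75) +
            meal_pulse_kernel(times - 18.5, 0.75)))
      st_mu <- ref$basal_st + es * design$gain[["st"]] * s$latent
      hr_mu <- s$s_hr * (ref$basal_hr + es * design$gain[["hr"]] * s$latent)
      tibble(
        subject_id = s$subject_id, repeat_id = seq_len(design$repeats),
        time = times,
        cortisol = rnorm_pos(cort_mu, design$noise$cortisol),
        glucose = rnorm_pos(gluc_mu, design$noise$glucose),
        st = rnorm_pos(rep(st_mu, design$repeats), design$noise$st),
        hr = rnorm_pos(rep(hr_mu, design$repeats), design$noise$hr)
      )
    })

    subjects$scl90 <- generate_scale_scores(subjects$latent, "SCL90",
      noise_sd = design$scale_noise_sd * 4
    )
    subjects$sds <- generate_scale_scores(subjects$latent, "SDS",
      noise_sd = design$scale_noise_sd
    )
    subjects$sas <- generate_scale_scores(subjects$latent, "SAS",
      noise_sd = design$scale_noise_sd
    )
    subjects$stais <- generate_scale_scores(subjects$latent, "STAIS",
      noise_sd = design$scale_noise_sd
    )

    dplyr::left_join(
      rows,
      dplyr::select(
        subjects, "subject_id", "group", "latent", "gender", "age",
        "height", "weight", "mean_bp", "scl90", "sds", "sas", "stais"
      ),
      by = "subject_id"
    )
  })
}
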