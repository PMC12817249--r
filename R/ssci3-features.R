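FEATURE_COLS <- c(
  "cortisol_adj", "glucose_adj", "st", "hr",
  "gender", "age", "height", "weight", "mean_bp"
)

#' Assemble model input features from cohort records
#'
#' Builds the 9-element feature vector per record: cortisol and glucose
#' (retro-adjusted to the benchmark clock time via the fitted baselines
#' when `temporal = TRUE`, raw otherwise), skin temperature, heart rate,
#' and the demographic features (gender encoded 0/1, age, height, weight,
#' mean blood pressure). Records measured at the benchmark time are
#' unchanged by adjustment.
#'
#' Normalisation is deliberately separate (see [fit_normalization()]) so
#' that its parameters can be estimated on training data only.
#'
#' @param records Cohort tibble with columns `time`, `cortisol`, `glucose`,
#'   `st`, `hr`, `gender`, `age`, `height`, `weight`, `mean_bp`.
#' @param models Named list of `stressci_baseline` objects with elements
#'   `cortisol` and `glucose` (required when `temporal = TRUE`).
#' @param temporal Retro-adjust cortisol and glucose to the benchmark time?
#' @return Tibble of feature columns (`cortisol_adj`, `glucose_adj`, `st`,
#'   `hr`, `gender`, `age`, `height`, `weight`, `mean_bp`).
#' @export
assemble_features <- function(records, models = NULL, temporal = TRUE) {
  needed <- c("time", "cortisol", "glucose", "st", "hr", "gender", "age", "height", "weight", "mean_bp")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    abort(
      sprintf("Records are missing column(s): %s.", toString(missing_cols)),
      class = "stressci_missing_data"
    )
  }
  if (any(!stats::complete.cases(records[needed]))) {
    abort("Records contain missing values in required columns.", class = "stressci_missing_data")
  }
  if (temporal) {
    if (is.null(models$cortisol) || is.null(models$glucose)) {
      abort("`models` must provide cortisol and glucose baselines when temporal = TRUE.", class = "stressci_invalid_parameter")
    }
    cort <- retro_adjust(records$cortisol, records$time, models$cortisol)
    gluc <- retro_adjust(records$glucose, records$time, models$glucose)
  } else {
    cort <- records$cortisol
    gluc <- records$glucose
  }
  gender_num <- if (is.numeric(records$gender)) {
    records$gender
  } else {
    as.numeric(records$gender == "male")
  }
  tibble(
    cortisol_adj = cort, glucose_adj = gluc,
    st = records$st, hr = records$hr,
    gender = gender_num, age = records$age, height = records$height,
    weight = records$weight, mean_bp = records$mean_bp
  )
}

#' Fit min-max normalisation parameters on training features
#'
#' @param features Feature tibble from [assemble_features()].
#' @return A `stressci_norm` object (per-column min and range).
#' @export
fit_normalization <- function(features) {
  mins <- vapply(features, min, numeric(1))
  rngs <- vapply(features, function(x) diff(range(x)), numeric(1))
  rngs[rngs == 0] <- 1 # constant column maps to 0
  structure(list(min = mins, range = rngs, cols = names(features)),
    class = "stressci_norm"
  )
}

#' Apply fitted min-max normalisation
#'
#' Applying training-fitted parameters to test data never consults the test
#' distribution, preventing information leakage.
#'
#' @param features Feature tibble.
#' @param norm A `stressci_norm` from [fit_normalization()].
#' @return Normalised feature tibble.
#' @export
apply_normalization <- function(features, norm) {
  stopifnot(inherits(norm, "stressci_norm"))
  out <- features
  for (cn in norm$cols) {
    out[[cn]] <- (features[[cn]] - norm$min[[cn]]) / norm$range[[cn]]
  }
  out
}

#' Depression label from the three chronic-stress scales
#'
#' Computes the composite severity score as a weighted sum of the min-max
#' normalised SCL-90, SDS and SAS scores (equal thirds by default), assigns
#' the four-group label (ND, DR, MD, SD) by three increasing thresholds
#' (composites exactly at a threshold go to the higher class), and derives
#' the binary label: MD and SD form the patient group, ND and DR the
#' healthy-control group.
#'
#' @param scl90,sds,sas Scale scores (vectors), within their admissible
#'   ranges.
#' @param weights Length-3 non-negative weights for (SCL-90, SDS, SAS).
#' @param thresholds Three increasing composite cutpoints for DR/MD/SD.
#' @return Tibble with `composite_score`, `class4` (factor ND<DR<MD<SD) and
#'   `class2` (factor healthy/patient).
#' @export
#' @examples
#' label_from_scales(90, 25, 25)$class4 # ND at all-scale minimum
label_from_scales <- function(scl90, sds, sas,
                              weights = c(1, 1, 1) / 3,
                              thresholds = c(0.14, 0.33, 0.52)) {
  if (length(weights) != 3L || any(weights < 0)) {
    abort("`weights` must be three non-negative values.", class = "stressci_config_error")
  }
  if (length(thresholds) != 3L || is.unsorted(thresholds, strictly = TRUE)) {
    abort("`thresholds` must be three increasing values.", class = "stressci_config_error")
  }
  scores <- list(SCL90 = scl90, SDS = sds, SAS = sas)
  norm <- purrr::imap(scores, function(x, kind) {
    r <- scale_range(kind)
    if (any(x < r[1] - 1e-9) || any(x > r[2] + 1e-9)) {
      abort(
        sprintf("%s score out of admissible range [%g, %g].", kind, r[1], r[2]),
        class = "stressci_invalid_parameter"
      )
    }
    (x - r[1]) / (r[2] - r[1])
  })
  composite <- weights[1] * norm$SCL90 + weights[2] * norm$SDS + weights[3] * norm$SAS
  # right = FALSE: a composite exactly at a threshold takes the higher class
  class4 <- cut(composite,
    breaks = c(-Inf, thresholds, Inf), right = FALSE,
    labels = c("ND", "DR", "MD", "SD")
  )
  class2 <- factor(ifelse(class4 %in% c("MD", "SD"), "patient", "healthy"),
    levels = c("healthy", "patient")
  )
  tibble(composite_score = composite, class4 = class4, class2 = class2)
}

#' Subject-level train/test split of a cohort
#'
#' Holds out whole subjects (never splitting one subject's repeated records
#' across partitions, which would leak identity information). With the
#' default 49-subject, 3-repeat design and 10 held-out subjects the split
#' is exactly 117 training and 30 test records (about 4:1).
#'
#' @param table Cohort tibble with a `subject_id` column.
#' @param test_subjects Number of subjects to hold out (default 10).
#' @param seed Integer seed for the subject draw.
#' @return List with `train` and `test` tibbles.
#' @export
#' @examples
#' cohort <- generate_depression_cohort(seed = 1)
#' sp <- split_cohort(cohort, test_subjects = 10, seed = 1)
#' nrow(sp$train) # 117
split_cohort <- function(table, test_subjects = 10, seed = 1) {
  if (!"subject_id" %in% names(table)) {
    abort("`table` needs a `subject_id` column.", class = "stressci_schema_error")
  }
  ids <- unique(table$subject_id)
  if (test_subjects >= length(ids)) {
    abort("`test_subjects` must be fewer than the number of subjects.", class = "stressci_invalid_parameter")
  }
  reps <- table(table$subject_id)
  if (length(unique(reps)) != 1L) {
    warn("Repeats per subject are not uniform; split sizes will vary with the draw.")
  }
  test_ids <- with_seed_or_current(seed, sample(ids, test_subjects))
  list(
    train = dplyr::filter(table, !(.data$subject_id %in% test_ids)),
    test = dplyr::filter(table, .data$subject_id %in% test_ids)
  )
}
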