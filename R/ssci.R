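BIOMARKERS <- c("cortisol", "glucose", "st", "hr")

#' Unweighted composite stress index (relative-change sum)
#'
#' The first composite stress index is the algebraic superposition of
#' relative changes of each panel biomarker against its control value:
#' `sum_i (measure_i - control_i) / control_i`. The control value is the
#' value before the start of a test or during a stable period; using
#' relative changes minimises inter-individual level differences.
#'
#' @param measure Named numeric vector, one-row data frame, or panel tibble
#'   with columns among `cortisol`, `glucose`, `st`, `hr` (a tibble yields
#'   one index per row).
#' @param control Named numeric vector (or one-row data frame) of positive
#'   control values covering `included`.
#' @param included Biomarkers to include (default all four).
#' @return Numeric index value(s), dimensionless.
#' @export
#' @examples
#' compute_ssci1(
#'   c(cortisol = 120, glucose = 90, st = 33, hr = 70),
#'   c(cortisol = 100, glucose = 100, st = 33, hr = 70)
#' )
compute_ssci1 <- function(measure, control, included = BIOMARKERS) {
  if (is.data.frame(control)) control <- unlist(control[1, , drop = TRUE])
  included <- match.arg(included, BIOMARKERS, several.ok = TRUE)
  missing_m <- setdiff(included, names(measure))
  if (length(missing_m)) {
    abort(sprintf("`measure` is missing biomarker(s): %s.", toString(missing_m)), class = "stressci_key_error")
  }
  missing_c <- setdiff(included, names(control))
  if (length(missing_c)) {
    abort(sprintf("`control` is missing biomarker(s): %s.", toString(missing_c)), class = "stressci_key_error")
  }
  ctrl <- unlist(control[included])
  if (any(!is.finite(ctrl)) || any(ctrl <= 0)) {
    abort("Control values must be positive and finite.", class = "stressci_degenerate_control")
  }
  if (is.data.frame(measure)) {
    dev <- purrr::map(included, function(b) (measure[[b]] - ctrl[[b]]) / ctrl[[b]])
    Reduce(`+`, dev)
  } else {
    sum((unlist(measure[included]) - ctrl) / ctrl)
  }
}

#' Temporally coupled relative deviation of a measurement
#'
#' Evaluates a measurement against the fitted circadian baseline at its own
#' clock time: `(value - B(t)) / B(t)`. This deviation is invariant under
#' multiplicative retro-adjustment to the benchmark time, which is why the
#' weighted index built from it is comparable across measurement times.
#'
#' @param value Measured biomarker value(s).
#' @param t Measurement clock time(s), within the model window.
#' @param model A `stressci_baseline` for that biomarker.
#' @return Dimensionless relative deviation(s).
#' @export
relative_deviation_t <- function(value, t, model) {
  bt <- baseline_at(model, t)
  floor_val <- 1e-6 * mean(abs(bt))
  if (any(abs(bt) < floor_val) || any(bt <= 0)) {
    abort("Degenerate baseline value; cannot form relative deviation.", class = "stressci_degenerate_baseline")
  }
  (value - bt) / bt
}

#' Estimate per-biomarker impact weights by multiple linear regression
#'
#' Ordinary least squares of psychometric stress scores (STAI-S) on the
#' temporally coupled relative deviations of the included biomarkers, with
#' an intercept. The fitted coefficients are the impact weights of each
#' evaluation metric on the stress state.
#'
#' @param deviations Data frame or matrix (`n x k`) of per-biomarker
#'   relative deviations; column names are the biomarker names.
#' @param stais_scores Numeric vector of length `n` of stress scores.
#' @return A `stressci_weights` object: list with `weights` (named),
#'   `intercept`, `included_biomarkers`, `fit_r2`, `n_fit`, `conf_int`
#'   (95% CIs for the weights) and the underlying `lm` fit.
#' @export
#' @examples
#' d <- data.frame(cortisol = runif(30), glucose = runif(30), hr = runif(30))
#' y <- 30 + 10 * d$cortisol + 5 * d$glucose + 2 * d$hr
#' estimate_weights_mlr(d, y)$weights
estimate_weights_mlr <- function(deviations, stais_scores) {
  X <- as.data.frame(deviations)
  n <- nrow(X)
  k <- ncol(X)
  if (length(stais_scores) != n) {
    abort("`stais_scores` length must match rows of `deviations`.", class = "stressci_invalid_parameter")
  }
  if (n <= k + 1) {
    abort(
      sprintf("Need more than %d observations to fit %d weights.", k + 1, k),
      class = "stressci_insufficient_data"
    )
  }
  qrX <- qr(cbind(1, as.matrix(X)))
  if (qrX$rank < k + 1) {
    abort("Design matrix is rank deficient (collinear deviations).", class = "stressci_collinearity_error")
  }
  df <- cbind(.score = stais_scores, X)
  fit <- lm(.score ~ ., data = df)
  cf <- coef(fit)
  ci <- stats::confint(fit, level = 0.95)
  structure(
    list(
      weights = cf[-1], intercept = unname(cf[1]),
      included_biomarkers = names(X),
      fit_r2 = summary(fit)$r.squared, n_fit = n,
      conf_int = ci[-1, , drop = FALSE], fit = fit
    ),
    class = "stressci_weights"
  )
}

#' @export
print.stressci_weights <- function(x, ...) {
  cat(sprintf(
    "<stressci_weights> n=%d, R2=%.3f, intercept=%.3f\n", x$n_fit, x$fit_r2, x$intercept
  ))
  print(round(x$weights, 4))
  invisible(x)
}

#' Weighted temporally coupled composite stress index
#'
#' The second composite stress index: the weighted sum of the temporally
#' coupled relative deviations, `sum_i w_i * dev_i`. With
#' `with_intercept = TRUE` the regression intercept is added, putting the
#' index on the STAI-S score scale so the 34/44 cutpoints of
#' [classify_as_state()] apply; the intercept-free sum is the literal index
#' value.
#'
#' @param deviations Named numeric vector (or one-row data frame) of
#'   per-biomarker relative deviations covering the weight vector's
#'   included biomarkers.
#' @param weights A `stressci_weights` object, or a named numeric vector
#'   (then `intercept` supplies the offset).
#' @param with_intercept Add the intercept (default `TRUE`).
#' @param intercept Intercept when `weights` is a bare vector.
#' @return Index value (score scale if `with_intercept`).
#' @export
#' @examples
#' compute_ssci2(c(a = 0.2, b = 0.1, c = 0.05),
#'   weights = c(a = 10, b = 5, c = 2), with_intercept = FALSE
#' )
compute_ssci2 <- function(deviations, weights, with_intercept = TRUE, intercept = 0) {
  if (inherits(weights, "stressci_weights")) {
    w <- weights$weights
    names(w) <- weights$included_biomarkers
    b0 <- weights$intercept
  } else {
    w <- weights
    b0 <- intercept
  }
  if (is.data.frame(deviations)) deviations <- unlist(deviations[1, , drop = TRUE])
  missing_b <- setdiff(names(w), names(deviations))
  if (length(missing_b)) {
    abort(
      sprintf("`deviations` is missing included biomarker(s): %s.", toString(missing_b)),
      class = "stressci_key_error"
    )
  }
  out <- sum(w * unlist(deviations[names(w)]))
  if (with_intercept) out <- out + b0
  out
}

#' Classify the acute-stress state from an evaluation score
#'
#' Three-way classification of the acute-stress (AS) state on the STAI-S
#' score scale using 34 and 44 as critical points: scores below 34 are
#' Non-AS, scores in `[34, 44)` are Low AS, and scores of 44 or more are
#' High AS (left-closed intervals).
#'
#' @param score Evaluation score(s) on the STAI-S scale.
#' @param cutpoints Length-2 increasing numeric vector, default `c(34, 44)`.
#' @return Factor with levels `NonAS`, `LowAS`, `HighAS`.
#' @export
#' @examples
#' classify_as_state(c(30, 40, 44))
classify_as_state <- function(score, cutpoints = c(34, 44)) {
  if (any(!is.finite(score))) {
    abort("`score` must be finite.", class = "stressci_invalid_parameter")
  }
  if (length(cutpoints) != 2L || cutpoints[1] >= cutpoints[2]) {
    abort("`cutpoints` must be two increasing values.", class = "stressci_config_error")
  }
  cut(score,
    breaks = c(-Inf, cutpoints, Inf), right = FALSE,
    labels = c("NonAS", "LowAS", "HighAS")
  )
}

#' First warning-trigger time of an index stream
#'
#' Scans a time-ordered stream of composite-index values and returns the
#' earliest point at which the value reaches `fraction` (default 80%) of a
#' reference maximum. The reference maximum is typically the peak index
#' recorded in a prior calibration session; passing
#' `reference_max = "running"` instead uses the running maximum of the
#' stream itself (an online mode that a retrospective calibration cannot
#' reproduce exactly).
#'
#' @param ssci1_stream Numeric index values in time order.
#' @param reference_max Positive reference maximum, or `"running"`.
#' @param fraction Trigger fraction in `(0, 1]`, default 0.8.
#' @param times Optional time stamps aligned with the stream.
#' @return A list with `triggered` (logical), `index` (position or `NA`)
#'   and `time` (stamp or `NA`).
#' @export
#' @examples
#' warning_trigger(c(0.1, 0.5, 0.85, 0.9), reference_max = 1)$index
warning_trigger <- function(ssci1_stream, reference_max, fraction = 0.8, times = NULL) {
  check_numeric_vector(ssci1_stream, "ssci1_stream")
  check_number(fraction, "fraction", min = 1e-12, max = 1)
  if (identical(reference_max, "running")) {
    threshold <- fraction * cummax(ssci1_stream)
    hit <- which(ssci1_stream >= threshold & cummax(ssci1_stream) > 0)
  } else {
    check_number(reference_max, "reference_max")
    if (reference_max <= 0) {
      abort("`reference_max` must be positive.", class = "stressci_invalid_parameter")
    }
    hit <- which(ssci1_stream >= fraction * reference_max)
  }
  idx <- if (length(hit)) hit[1] else NA_integer_
  list(
    triggered = length(hit) > 0,
    index = idx,
    time = if (!is.na(idx) && !is.null(times)) times[idx] else NA_real_
  )
}
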