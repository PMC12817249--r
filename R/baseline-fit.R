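#' Seasonal-trend decomposition of a biomarker series
#'
#' Resamples an irregular (time, value) series onto a uniform grid by linear
#' interpolation and applies seasonal-trend decomposition by loess (STL),
#' returning additive `trend`, `seasonal` and `residual` components whose
#' sum reconstructs the resampled series exactly. Used to characterise the
#' dominant temporal structure of a biomarker before choosing a parametric
#' baseline family.
#'
#' @param series Data frame with `time` (hours) and `value` columns.
#' @param period Cycle length in hours (24 for circadian structure).
#' @param n_grid Number of uniform grid points (default keeps the input
#'   density, minimum 4 samples per period).
#' @return A tibble with columns `time`, `value` (resampled), `trend`,
#'   `seasonal`, `residual`.
#' @export
#' @examples
#' t <- seq(0, 72, by = 0.5)
#' s <- tibble::tibble(time = t, value = 10 + 3 * sin(2 * pi * t / 24) + 0.05 * t)
#' dec <- stl_characterize(s, period = 24)
#' cor(dec$seasonal, sin(2 * pi * dec$time / 24))
stl_characterize <- function(series, period = 24, n_grid = NULL) {
  if (!all(c("time", "value") %in% names(series))) {
    abort("`series` needs `time` and `value` columns.", class = "stressci_schema_error")
  }
  series <- dplyr::arrange(as_tibble(series), .data$time)
  span <- diff(range(series$time))
  if (span < 2 * period) {
    abort(
      sprintf("Series spans %.2f h; need at least two periods (%.0f h).", span, 2 * period),
      class = "stressci_insufficient_data"
    )
  }
  n_grid <- n_grid %||% max(nrow(series), ceiling(4 * span / period) + 1)
  grid <- seq(min(series$time), max(series$time), length.out = n_grid)
  value <- stats::approx(series$time, series$value, xout = grid)$y
  dt <- grid[2] - grid[1]
  freq <- max(round(period / dt), 2L)
  fit <- stats::stl(stats::ts(value, frequency = freq), s.window = "periodic")
  comp <- fit$time.series
  tibble(
    time = grid, value = value,
    trend = as.numeric(comp[, "trend"]),
    seasonal = as.numeric(comp[, "seasonal"]),
    residual = as.numeric(comp[, "remainder"])
  )
}

#' Fit a parametric day-curve baseline to a biomarker series
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of one model family
#' to (time, value) data, with deterministic initialisation (mesor = data
#' mean, amplitude = half the data range, acrophase = argmax time) and box
#' bounds derived from the data range unless supplied. The constant family
#' is solved in closed form (the mean). The fit is deterministic given the
#' data: no random restarts.
#'
#' @param series Data frame with `time` (clock-hours) and `value` columns.
#' @param family One of [baseline_families()].
#' @param biomarker Optional biomarker name carried in the result.
#' @param bounds Optional list with named `lower` and `upper` vectors.
#' @param max_evals Maximum residual-function evaluations (default 5000).
#' @param window Day window (clock-hours) over which the baseline is
#'   considered valid; default 08:00-22:00.
#' @param benchmark_time Benchmark clock time for retro-adjustment
#'   (default 08:00).
#' @return A `stressci_baseline` object with elements `family`, `params`,
#'   `mse`, `loocv_loss` (`NA` until model selection), `window`,
#'   `benchmark_time`, `n`, `biomarker`.
#' @export
#' @examples
#' t <- seq(8, 22, length.out = 14)
#' v <- 150 + 100 * cos(2 * pi * (t - 14) / 24)
#' fit <- fit_baseline(tibble::tibble(time = t, value = v), "cosinor")
#' round(fit$params, 4)
fit_baseline <- function(series, family, biomarker = NULL, bounds = NULL,
                         max_evals = 5000, window = DAY_WINDOW,
                         benchmark_time = 8) {
  if (!all(c("time", "value") %in% names(series))) {
    abort("`series` needs `time` and `value` columns.", class = "stressci_schema_error")
  }
  fam <- baseline_family(family)
  time <- as.numeric(series$time)
  value <- as.numeric(series$value)
  if (any(!is.finite(time)) || any(!is.finite(value))) {
    abort("Series contains non-finite values.", class = "stressci_invalid_parameter")
  }
  npar <- length(fam$par_names)
  if (length(time) < npar + 2) {
    abort(
      sprintf("Need at least %d points to fit '%s'; got %d.", npar + 2, family, length(time)),
      class = "stressci_insufficient_data"
    )
  }

  if (family == "constant") {
    params <- c(level = mean(value))
    mse <- mean((value - mean(value))^2)
  } else {
    init <- fam$init(time, value)
    b <- bounds %||% fam$bounds(time, value)
    fit <- minpack.lm::nls.lm(
      par = init,
      lower = b$lower[fam$par_names], upper = b$upper[fam$par_names],
      fn = function(p) value - fam$predict(p, time),
      control = minpack.lm::nls.lm.control(maxfev = max_evals, maxiter = min(max_evals, 1024))
    )
    if (fit$info == 0 || fit$info == 9) {
      cnd <- rlang::error_cnd(
        class = "stressci_convergence_error",
        message = sprintf("Fit of '%s' did not converge within %d evaluations.", family, max_evals),
        best_params = fit$par
      )
      rlang::cnd_signal(cnd)
    }
    params <- unlist(fit$par)
    mse <- mean(fit$fvec^2)
  }

  structure(
    list(
      biomarker = biomarker, family = family, params = params,
      mse = mse, loocv_loss = NA_real_, window = window,
      benchmark_time = benchmark_time, n = length(time)
    ),
    class = "stressci_baseline"
  )
}

#' @export
print.stressci_baseline <- function(x, ...) {
  cat(sprintf(
    "<stressci_baseline>%s family=%s, n=%d, mse=%.4g%s\n",
    if (is.null(x$biomarker)) "" else paste0(" ", x$biomarker),
    x$family, x$n, x$mse,
    if (is.na(x$loocv_loss)) "" else sprintf(", loocv=%.4g", x$loocv_loss)
  ))
  print(round(x$params, 4))
  invisible(x)
}

#' Select a baseline family by leave-one-out cross-validation
#'
#' For each candidate family, each observation is held out in turn, the
#' model is refit on the remainder, and the squared prediction error on the
#' held-out point is recorded; the family with the smallest average loss is
#' refit on all data and returned with its LOOCV loss attached. Families
#' that fail to fit on any fold are dropped (with a warning).
#'
#' @inheritParams fit_baseline
#' @param candidate_families Character vector of families to compare.
#' @return A `stressci_baseline` for the winning family, with `loocv_loss`
#'   set and an attribute `loocv_losses` giving every family's average loss.
#' @export
#' @examples
#' t <- seq(8, 22, length.out = 14)
#' v <- 150 + 100 * cos(2 * pi * (t - 14) / 24) + rnorm(14, sd = 5)
#' m <- select_model_loocv(tibble::tibble(time = t, value = v),
#'   candidate_families = c("cosinor", "constant")
#' )
#' m$family
select_model_loocv <- function(series, candidate_families = c("cosinor", "constant"),
                               biomarker = NULL, max_evals = 5000,
                               window = DAY_WINDOW, benchmark_time = 8) {
  series <- as_tibble(series)
  n <- nrow(series)
  if (n < 5) {
    abort("Need at least 5 points for LOOCV model selection.", class = "stressci_insufficient_data")
  }
  losses <- purrr::map_dbl(candidate_families, function(famname) {
    fam <- baseline_family(famname)
    if (n - 1 < length(fam$par_names) + 2) {
      return(NA_real_)
    }
    errs <- vapply(seq_len(n), function(i) {
      fit <- tryCatch(
        fit_baseline(series[-i, ], famname,
          max_evals = max_evals,
          window = window, benchmark_time = benchmark_time
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        return(NA_real_)
      }
      pred <- predict_baseline(fit, series$time[i])
      (series$value[i] - pred)^2
    }, numeric(1))
    if (any(is.na(errs))) NA_real_ else mean(errs)
  })
  names(losses) <- candidate_families
  if (all(is.na(losses))) {
    abort("No candidate family could be fit on all LOOCV folds.", class = "stressci_model_selection_error")
  }
  if (any(is.na(losses))) {
    warn(sprintf("Dropped families failing LOOCV folds: %s.", toString(candidate_families[is.na(losses)])))
  }
  best <- candidate_families[which.min(losses)]
  model <- fit_baseline(series, best,
    biomarker = biomarker, max_evals = max_evals,
    window = window, benchmark_time = benchmark_time
  )
  model$loocv_loss <- unname(losses[best])
  attr(model, "loocv_losses") <- losses
  model
}

# Raw family prediction without window checks (used by LOOCV and plotting).
predict_baseline <- function(model, t) {
  fam <- baseline_family(model$family)
  fam$predict(as.list(model$params), t)
}

#' Evaluate a fitted baseline at clock times
#'
#' @param model A `stressci_baseline`.
#' @param t Clock-hours within the model window.
#' @return Baseline value(s) `B(t)`.
#' @export
baseline_at <- function(model, t) {
  stopifnot(inherits(model, "stressci_baseline"))
  check_numeric_vector(t, "t")
  if (any(t < model$window[1] | t > model$window[2])) {
    abort(
      sprintf(
        "Time(s) outside the model window [%.1f, %.1f].",
        model$window[1], model$window[2]
      ),
      class = "stressci_out_of_window"
    )
  }
  predict_baseline(model, t)
}

#' Retro-adjust a measurement to the benchmark clock time
#'
#' Maps a value measured at clock time `t` to its equivalent at the model's
#' benchmark time via the multiplicative rule
#' `adjusted = value * B(benchmark) / B(t)`. The rule is ratio-preserving:
#' the relative deviation `(value - B(t)) / B(t)` is exactly invariant under
#' it, which is what makes temporally coupled indices comparable across
#' measurement times. It is the identity at the benchmark time.
#'
#' @param value Measured value(s).
#' @param t Measurement clock time(s), within the model window.
#' @param model A `stressci_baseline`.
#' @return Adjusted value(s) at the benchmark time.
#' @export
#' @examples
#' t <- seq(8, 22, length.out = 14)
#' v <- 150 + 100 * cos(2 * pi * (t - 14) / 24)
#' m <- fit_baseline(tibble::tibble(time = t, value = v), "cosinor")
#' retro_adjust(200, 14, m)
retro_adjust <- function(value, t, model) {
  stopifnot(inherits(model, "stressci_baseline"))
  bt <- baseline_at(model, t)
  bb <- baseline_at(model, model$benchmark_time)
  floor_val <- 1e-6 * mean(abs(c(bt, bb)))
  if (any(bt < floor_val) || any(bb < floor_val)) {
    abort("Baseline value below positivity floor; cannot retro-adjust.", class = "stressci_degenerate_baseline")
  }
  value * bb / bt
}
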