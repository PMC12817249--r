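#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted baseline model
#'
#' @param x A `stressci_baseline`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.stressci_baseline <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params))
}

#' One-row summary of a fitted baseline model
#'
#' @param x A `stressci_baseline`.
#' @param ... Unused.
#' @return Tibble with `biomarker`, `family`, `n`, `mse`, `loocv_loss`,
#'   `benchmark_time`.
#' @export
glance.stressci_baseline <- function(x, ...) {
  tibble(
    biomarker = x$biomarker %||% NA_character_, family = x$family,
    n = x$n, mse = x$mse, loocv_loss = x$loocv_loss,
    benchmark_time = x$benchmark_time
  )
}

#' Tidy an impact-weight vector
#'
#' @param x A `stressci_weights`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, and 95% CI bounds when
#'   available.
#' @export
tidy.stressci_weights <- function(x, ...) {
  out <- tibble(
    term = c("(Intercept)", names(x$weights)),
    estimate = c(x$intercept, unname(x$weights))
  )
  if (!is.null(x$conf_int)) {
    out$conf.low <- c(NA_real_, x$conf_int[, 1])
    out$conf.high <- c(NA_real_, x$conf_int[, 2])
  }
  out
}

#' One-row summary of an impact-weight fit
#'
#' @param x A `stressci_weights`.
#' @param ... Unused.
#' @return Tibble with `r.squared`, `n`, `n_biomarkers`.
#' @export
glance.stressci_weights <- function(x, ...) {
  tibble(
    r.squared = x$fit_r2, n = x$n_fit,
    n_biomarkers = length(x$included_biomarkers)
  )
}

#' Tidy a classifier evaluation
#'
#' @param x A `stressci_eval`.
#' @param ... Unused.
#' @return The per-algorithm metrics tibble.
#' @export
tidy.stressci_eval <- function(x, ...) x$summary
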