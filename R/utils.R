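#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats coef lm median predict qnorm runif rnorm sd setNames var
NULL

# Clock times are decimal hours: 8.25 == 08:15. The day window used for all
# baseline fitting is [8, 22].
DAY_WINDOW <- c(8, 22)

#' Evaluate code with a temporary RNG seed
#'
#' All stochastic generators in the package funnel their randomness through
#' this helper so that identical arguments plus an identical seed give
#' bit-identical output, and so that calling them never disturbs the caller's
#' RNG state.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed_or_current <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# Gaussian noise truncated at zero around positive means: samples from
# N(mean, sd) conditioned on being > 0, via inverse-CDF so it is vectorised
# and deterministic under a seed. Preserves strict positivity of biomarker
# series by construction.
rnorm_pos <- function(mean, sd) {
  if (all(sd == 0)) {
    return(mean)
  }
  lo <- stats::pnorm(0, mean = mean, sd = sd)
  u <- runif(length(mean), min = lo, max = 1)
  stats::qnorm(u, mean = mean, sd = sd)
}

check_number <- function(x, name, min = -Inf, max = Inf, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) {
      return(invisible(x))
    }
    abort(sprintf("`%s` must be a number, not NULL.", name), class = "stressci_invalid_parameter")
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name), class = "stressci_invalid_parameter")
  }
  if (x < min || x > max) {
    abort(
      sprintf("`%s` must be in [%s, %s], got %s.", name, format(min), format(max), format(x)),
      class = "stressci_invalid_parameter"
    )
  }
  invisible(x)
}

check_numeric_vector <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x))) {
    abort(sprintf("`%s` must be a non-empty finite numeric vector.", name), class = "stressci_invalid_parameter")
  }
  if (any(x < min)) {
    abort(sprintf("`%s` must be >= %s.", name, format(min)), class = "stressci_invalid_parameter")
  }
  invisible(x)
}

check_clock_hours <- function(x, name) {
  check_numeric_vector(x, name)
  if (any(x < 0 | x >= 24)) {
    abort(sprintf("`%s` must contain clock-hours in [0, 24).", name), class = "stressci_invalid_parameter")
  }
  invisible(x)
}

# Relative standard deviation (coefficient of variation), in percent.
#' Relative standard deviation
#'
#' @param x Numeric vector with non-zero mean.
#' @return `100 * sd(x) / abs(mean(x))` (percent).
#' @export
#' @examples
#' rsd(c(95, 100, 105))
rsd <- function(x) {
  check_numeric_vector(x, "x")
  100 * stats::sd(x) / abs(mean(x))
}
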