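# Registry of candidate day-curve families for circadian baseline fitting.
# Each entry provides: parameter names, a prediction function, a
# deterministic initialisation rule (mesor = data mean, amplitude = half
# range, acrophase = argmax time), and default box bounds derived from the
# data range. Angular frequency is fixed at one cycle per 24 h.
OMEGA24 <- 2 * pi / 24

baseline_family <- function(name) {
  fam <- BASELINE_FAMILIES[[name]]
  if (is.null(fam)) {
    abort(
      sprintf(
        "Unknown baseline family '%s'. Available: %s.",
        name, toString(names(BASELINE_FAMILIES))
      ),
      class = "stressci_invalid_parameter"
    )
  }
  fam
}

BASELINE_FAMILIES <- list(
  constant = list(
    par_names = "level",
    predict = function(p, t) rep(p[["level"]], length(t)),
    init = function(time, value) c(level = mean(value)),
    bounds = function(time, value) {
      list(lower = c(level = -Inf), upper = c(level = Inf))
    }
  ),
  cosinor = list(
    par_names = c("mesor", "amplitude", "acrophase"),
    predict = function(p, t) {
      p[["mesor"]] + p[["amplitude"]] * cos(OMEGA24 * (t - p[["acrophase"]]))
    },
    init = function(time, value) {
      c(
        mesor = mean(value), amplitude = diff(range(value)) / 2,
        acrophase = time[which.max(value)]
      )
    },
    bounds = function(time, value) {
      a0 <- time[which.max(value)]
      list(
        lower = c(mesor = min(value), amplitude = 0, acrophase = a0 - 12),
        upper = c(
          mesor = max(value), amplitude = 2 * diff(range(value)),
          acrophase = a0 + 12
        )
      )
    }
  ),
  harmonic2 = list(
    par_names = c("mesor", "amp1", "phase1", "amp2", "phase2"),
    predict = function(p, t) {
      p[["mesor"]] +
        p[["amp1"]] * cos(OMEGA24 * (t - p[["phase1"]])) +
        p[["amp2"]] * cos(2 * OMEGA24 * (t - p[["phase2"]]))
    },
    init = function(time, value) {
      c(
        mesor = mean(value), amp1 = diff(range(value)) / 2,
        phase1 = time[which.max(value)], amp2 = diff(range(value)) / 8,
        phase2 = time[which.max(value)]
      )
    },
    bounds = function(time, value) {
      a0 <- time[which.max(value)]
      r <- diff(range(value))
      list(
        lower = c(mesor = min(value), amp1 = 0, phase1 = a0 - 12, amp2 = 0, phase2 = a0 - 12),
        upper = c(mesor = max(value), amp1 = 2 * r, phase1 = a0 + 12, amp2 = r, phase2 = a0 + 12)
      )
    }
  ),
  skewed_peak = list(
    par_names = c("basal", "amplitude", "acrophase", "kappa", "skew"),
    predict = function(p, t) {
      p[["basal"]] + p[["amplitude"]] *
        day_curve_shape(t, p[["acrophase"]], p[["kappa"]], p[["skew"]])
    },
    init = function(time, value) {
      c(
        basal = min(value), amplitude = diff(range(value)),
        acrophase = time[which.max(value)], kappa = 2, skew = 0
      )
    },
    bounds = function(time, value) {
      a0 <- time[which.max(value)]
      r <- diff(range(value))
      list(
        lower = c(basal = 0, amplitude = 0, acrophase = a0 - 12, kappa = 0.2, skew = -0.9),
        upper = c(
          basal = max(value), amplitude = 4 * r, acrophase = a0 + 12,
          kappa = 10, skew = 0.9
        )
      )
    }
  ),
  meal_pulse = list(
    par_names = c("basal", "amplitude", "rise"),
    predict = function(p, t, meal_times = c(8, 12.5, 18.5)) {
      out <- rep(p[["basal"]], length(t))
      for (m in meal_times) {
        out <- out + p[["amplitude"]] * meal_pulse_kernel(t - m, p[["rise"]])
      }
      out
    },
    init = function(time, value) {
      c(basal = min(value), amplitude = diff(range(value)), rise = 0.75)
    },
    bounds = function(time, value) {
      r <- diff(range(value))
      list(
        lower = c(basal = 0, amplitude = 0, rise = 0.1),
        upper = c(basal = max(value), amplitude = 4 * r, rise = 4)
      )
    }
  )
)

#' Names of the candidate baseline model families
#'
#' @return Character vector: `constant`, `cosinor`, `harmonic2`,
#'   `skewed_peak`, `meal_pulse`.
#' @export
baseline_families <- function() names(BASELINE_FAMILIES)
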