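# Default intra-beat pulse morphology, expressed as fractions of the beat
# period so the waveform scales sensibly from 30 to 200 bpm. Amplitudes
# follow the percussion > tidal > dicrotic ordering of an arterial pulse.
PULSE_MORPHOLOGY <- list(
  amplitude = c(percussion = 1.0, tidal = 0.5, dicrotic = 0.25),
  offset_frac = c(percussion = 0.00, tidal = 0.22, dicrotic = 0.45),
  width_frac = c(percussion = 0.045, tidal = 0.07, dicrotic = 0.07)
)

#' Simulate a piezoresistive pulse waveform
#'
#' Builds a synthetic arterial pulse trace: per beat, the sum of three
#' Gaussian bumps (percussion, tidal and dicrotic waves, with decreasing
#' amplitude and fixed intra-beat offsets expressed as fractions of the beat
#' period) at beat period `60 / hr`, plus white Gaussian noise at the stated
#' signal-to-noise ratio. Ground-truth percussion-peak times are stored for
#' validating the heart-rate readout.
#'
#' @param hr Heart rate in bpm, between 30 and 200.
#' @param duration Trace duration in seconds (>= 10).
#' @param sample_rate Sampling frequency in Hz (default 1000).
#' @param snr_db Signal-to-noise ratio in dB; `Inf` for a noiseless trace.
#' @param seed Integer seed for the noise (or `NULL`).
#' @param morphology List with `amplitude`, `offset_frac`, `width_frac`
#'   components; see `PULSE_MORPHOLOGY` defaults.
#' @return A `stressci_pulse` object: list with `sample_rate`, `time`
#'   (seconds), `values` (a.u. voltage), `true_beat_times` (seconds), `hr`.
#' @export
#' @examples
#' tr <- simulate_pulse_trace(72, duration = 15, snr_db = 20, seed = 1)
#' length(tr$true_beat_times)
simulate_pulse_trace <- function(hr, duration = 30, sample_rate = 1000,
                                 snr_db = Inf, seed = NULL,
                                 morphology = PULSE_MORPHOLOGY) {
  check_number(hr, "hr", min = 30, max = 200)
  check_number(duration, "duration", min = 10)
  check_number(sample_rate, "sample_rate", min = 1e-9)
  if (!is.numeric(snr_db) || length(snr_db) != 1L || is.na(snr_db)) {
    abort("`snr_db` must be a single number (possibly Inf).", class = "stressci_invalid_parameter")
  }
  period <- 60 / hr
  # The narrowest bump bounds the bandwidth; require comfortable margin over
  # the Nyquist limit for its ~3-sigma spectral extent.
  min_width_s <- min(morphology$width_frac) * period
  max_freq <- 3 / (2 * pi * min_width_s)
  if (sample_rate < 2 * max_freq) {
    abort(
      sprintf(
        "`sample_rate` (%g Hz) is below the Nyquist requirement (%.1f Hz) for the pulse harmonics.",
        sample_rate, 2 * max_freq
      ),
      class = "stressci_invalid_parameter"
    )
  }

  t <- seq(0, duration, by = 1 / sample_rate)
  t <- t[t < duration]
  first_beat <- 0.5 * period
  beat_times <- seq(first_beat, duration - 0.25 * period, by = period)
  signal <- numeric(length(t))
  for (w in names(morphology$amplitude)) {
    a <- morphology$amplitude[[w]]
    off <- morphology$offset_frac[[w]] * period
    wid <- morphology$width_frac[[w]] * period
    for (b in beat_times) {
      signal <- signal + a * exp(-0.5 * ((t - b - off) / wid)^2)
    }
  }

  if (is.finite(snr_db)) {
    sig_power <- mean(signal^2)
    noise_sd <- sqrt(sig_power / 10^(snr_db / 10))
    noise <- with_seed_or_current(seed, rnorm(length(t), sd = noise_sd))
    signal <- signal + noise
  }

  structure(
    list(
      sample_rate = sample_rate, time = t, values = signal,
      true_beat_times = beat_times, hr = hr
    ),
    class = "stressci_pulse"
  )
}

#' @export
print.stressci_pulse <- function(x, ...) {
  cat(sprintf(
    "<stressci_pulse> %.1f s at %g Hz, %d true beats (hr %.0f bpm)\n",
    length(x$values) / x$sample_rate, x$sample_rate,
    length(x$true_beat_times), x$hr
  ))
  invisible(x)
}
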