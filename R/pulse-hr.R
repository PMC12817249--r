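#' Zero-phase band-pass filter a pulse trace
#'
#' Applies a Butterworth band-pass filter forward and backward
#' (zero-phase, so beat times are not biased by filter delay) to suppress
#' baseline drift and high-frequency noise. The default 0.5-5 Hz band covers
#' heart-rate fundamentals from 30 to 200 bpm plus low harmonics, and
#' removes the DC component.
#'
#' @param trace A `stressci_pulse` object or a numeric series (then
#'   `sample_rate` must be given).
#' @param low_hz,high_hz Band edges in Hz; `0 < low_hz < high_hz <`
#'   Nyquist.
#' @param sample_rate Sampling frequency in Hz (taken from the trace when
#'   omitted).
#' @param order Butterworth filter order (per pass).
#' @return Filtered numeric series, same length as the input.
#' @export
#' @examples
#' tr <- simulate_pulse_trace(60, duration = 15, seed = 1)
#' f <- bandpass_filter(tr)
bandpass_filter <- function(trace, low_hz = 0.5, high_hz = 5,
                            sample_rate = NULL, order = 2) {
  if (inherits(trace, "stressci_pulse")) {
    sample_rate <- trace$sample_rate
    x <- trace$values
  } else {
    x <- as.numeric(trace)
    if (is.null(sample_rate)) {
      abort("`sample_rate` is required for a bare numeric series.", class = "stressci_invalid_parameter")
    }
  }
  nyq <- sample_rate / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    abort(
      sprintf("Band [%g, %g] Hz must satisfy 0 < low < high < Nyquist (%g Hz).", low_hz, high_hz, nyq),
      class = "stressci_invalid_parameter"
    )
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  # demean first: the DC step otherwise excites long edge transients in the
  # forward-backward pass
  as.numeric(signal::filtfilt(bf, x - mean(x)))
}

#' Detect beat peaks in a filtered pulse series
#'
#' Finds local maxima whose height above the series minimum exceeds
#' `min_prominence` of the series range, enforcing a refractory period so no
#' two accepted peaks are closer than `refractory_s` (the higher peak wins;
#' for equal heights the earlier sample wins).
#'
#' @param filtered Numeric series (typically from [bandpass_filter()]).
#' @param sample_rate Sampling frequency in Hz.
#' @param refractory_s Minimum spacing between beats in seconds (default
#'   0.3 s, capping detectable HR at 200 bpm).
#' @param min_prominence Height threshold as a fraction of the series range.
#' @return Numeric vector of beat times in seconds (possibly empty).
#' @export
detect_peaks <- function(filtered, sample_rate, refractory_s = 0.3,
                         min_prominence = 0.4) {
  check_number(sample_rate, "sample_rate", min = 1e-9)
  check_number(refractory_s, "refractory_s", min = 1e-12)
  check_number(min_prominence, "min_prominence", min = 0, max = 1)
  x <- as.numeric(filtered)
  n <- length(x)
  if (n < 3L) {
    return(numeric(0))
  }
  rng <- diff(range(x))
  if (rng <= 0) {
    return(numeric(0))
  }
  threshold <- min(x) + min_prominence * rng

  # Strict-left, non-strict-right comparison makes the earliest sample of an
  # equal-height plateau the candidate.
  left <- x[2:(n - 1)] > x[1:(n - 2)]
  right <- x[2:(n - 1)] >= x[3:n]
  cand <- which(left & right) + 1L
  cand <- cand[x[cand] >= threshold]
  if (!length(cand)) {
    return(numeric(0))
  }

  # Greedy refractory pruning: accept candidates in decreasing height
  # (ties: earlier index first), rejecting any within refractory_s of an
  # accepted peak.
  ord <- cand[order(-x[cand], cand)]
  min_gap <- refractory_s * sample_rate
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(accepted - i) >= min_gap)) {
      accepted <- c(accepted, i)
    }
  }
  sort((accepted - 1L) / sample_rate)
}

#' Heart rate from beat times
#'
#' Converts detected beat times into a heart-rate estimate using the median
#' inter-beat interval (robust to an occasional missed or spurious beat).
#' With fewer than 3 beats the result is flagged `too_short` and the HR is
#' `NA`.
#'
#' @param beat_times Strictly increasing beat times in seconds.
#' @return A `stressci_hr` object: list with `beat_times`, `hr` (bpm or
#'   `NA`), `n_beats`, `quality_flag` (`"ok"`, `"low_snr"`, `"too_short"`).
#' @export
#' @examples
#' hr_from_peaks(seq(0, 10, by = 0.8))$hr # 75
hr_from_peaks <- function(beat_times) {
  beat_times <- as.numeric(beat_times)
  if (is.unsorted(beat_times, strictly = TRUE)) {
    abort("`beat_times` must be strictly increasing.", class = "stressci_invalid_parameter")
  }
  n <- length(beat_times)
  if (n < 3L) {
    return(structure(
      list(beat_times = beat_times, hr = NA_real_, n_beats = n, quality_flag = "too_short"),
      class = "stressci_hr"
    ))
  }
  ibi <- diff(beat_times)
  hr <- 60 / stats::median(ibi)
  # Wildly dispersed intervals indicate unreliable detection.
  flag <- if (stats::mad(ibi) / stats::median(ibi) > 0.25) "low_snr" else "ok"
  structure(
    list(beat_times = beat_times, hr = hr, n_beats = n, quality_flag = flag),
    class = "stressci_hr"
  )
}

#' @export
print.stressci_hr <- function(x, ...) {
  cat(sprintf(
    "<stressci_hr> hr = %s bpm from %d beats [%s]\n",
    if (is.na(x$hr)) "NA" else sprintf("%.1f", x$hr), x$n_beats, x$quality_flag
  ))
  invisible(x)
}

#' End-to-end heart-rate readout from a raw pulse trace
#'
#' Band-pass filters the raw waveform, detects beat peaks, and converts the
#' inter-beat intervals to bpm.
#'
#' @param trace A `stressci_pulse` object.
#' @inheritParams bandpass_filter
#' @inheritParams detect_peaks
#' @return A `stressci_hr` object (see [hr_from_peaks()]).
#' @export
#' @examples
#' tr <- simulate_pulse_trace(72, duration = 30, snr_db = 10, seed = 2)
#' estimate_hr(tr)$hr
estimate_hr <- function(trace, low_hz = 0.5, high_hz = 5,
                        refractory_s = 0.3, min_prominence = 0.4) {
  stopifnot(inherits(trace, "stressci_pulse"))
  filtered <- bandpass_filter(trace, low_hz, high_hz)
  beats <- detect_peaks(filtered, trace$sample_rate, refractory_s, min_prominence)
  hr_from_peaks(beats)
}
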