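PANEL_COLS <- c("subject_id", "time", "cortisol", "glucose", "st", "hr")

#' Read a biomarker panel CSV
#'
#' Reads and validates a panel file with header
#' `subject_id,time,cortisol,glucose,st,hr`. Times are decimal clock-hours
#' (8.25 = 08:15); `HH:MM` strings are accepted and converted. Malformed
#' rows are reported with their line numbers.
#'
#' @param path Path to a CSV file.
#' @return A validated panel tibble.
#' @export
read_panel <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(PANEL_COLS, names(raw))
  if (length(missing_cols)) {
    abort(
      sprintf("Panel file is missing column(s): %s.", toString(missing_cols)),
      class = "stressci_schema_error"
    )
  }
  # line number in the file: header is line 1
  line_no <- seq_len(nrow(raw)) + 1L

  time <- parse_clock_hours(raw$time)
  bad_time <- which(is.na(time) | time < 0 | time >= 24)
  if (length(bad_time)) {
    abort(
      sprintf("Invalid `time` at line(s) %s.", toString(line_no[bad_time])),
      class = "stressci_parse_error"
    )
  }
  out <- tibble(subject_id = raw$subject_id, time = time)
  for (b in c("cortisol", "glucose", "st", "hr")) {
    v <- suppressWarnings(as.numeric(raw[[b]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      abort(
        sprintf("Non-numeric `%s` at line(s) %s.", b, toString(line_no[bad])),
        class = "stressci_parse_error"
      )
    }
    neg <- which(v <= 0)
    if (length(neg)) {
      abort(
        sprintf("Non-positive `%s` at line(s) %s.", b, toString(line_no[neg])),
        class = "stressci_validation_error"
      )
    }
    out[[b]] <- v
  }
  out
}

# Accepts decimal hours ("14.25") or clock strings ("14:15").
parse_clock_hours <- function(x) {
  is_clock <- grepl("^\\d{1,2}:\\d{2}(:\\d{2})?$", x)
  out <- suppressWarnings(as.numeric(x))
  if (any(is_clock)) {
    parts <- strsplit(x[is_clock], ":", fixed = TRUE)
    out[is_clock] <- vapply(parts, function(p) {
      sum(as.numeric(p) / c(1, 60, 3600)[seq_along(p)])
    }, numeric(1))
  }
  out
}

#' Write a biomarker panel CSV
#'
#' @param panel Panel tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(panel[, intersect(c(PANEL_COLS, setdiff(names(panel), PANEL_COLS)), names(panel))], path)
  invisible(path)
}

#' Serialize a fitted baseline model to JSON
#'
#' @param model A `stressci_baseline`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_baseline_json <- function(model, path) {
  stopifnot(inherits(model, "stressci_baseline"))
  jsonlite::write_json(
    list(
      biomarker = model$biomarker, family = model$family,
      params = as.list(model$params), mse = model$mse,
      loocv_loss = model$loocv_loss, window = model$window,
      benchmark_time = model$benchmark_time, n = model$n
    ),
    path,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Read a baseline model from JSON
#'
#' @param path Path written by [write_baseline_json()].
#' @return A `stressci_baseline`.
#' @export
read_baseline_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      biomarker = x$biomarker, family = x$family, params = unlist(x$params),
      mse = x$mse, loocv_loss = x$loocv_loss %||% NA_real_,
      window = as.numeric(x$window), benchmark_time = x$benchmark_time,
      n = x$n
    ),
    class = "stressci_baseline"
  )
}

#' Serialize an impact-weight vector to JSON
#'
#' @param weights A `stressci_weights`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_weights_json <- function(weights, path) {
  stopifnot(inherits(weights, "stressci_weights"))
  jsonlite::write_json(
    list(
      weights = as.list(weights$weights), intercept = weights$intercept,
      included_biomarkers = weights$included_biomarkers,
      fit_r2 = weights$fit_r2, n_fit = weights$n_fit
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read an impact-weight vector from JSON
#'
#' @param path Path written by [write_weights_json()].
#' @return A `stressci_weights` (without the underlying `lm` fit).
#' @export
read_weights_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      weights = unlist(x$weights), intercept = x$intercept,
      included_biomarkers = x$included_biomarkers,
      fit_r2 = x$fit_r2, n_fit = x$n_fit, conf_int = NULL, fit = NULL
    ),
    class = "stressci_weights"
  )
}

#' Write a pulse trace as CSV with a JSON sidecar
#'
#' The two-column CSV holds `time_s` and `value`; the sidecar
#' (`<path>.json`) holds the sample rate and, for simulated traces, the
#' ground-truth beat times.
#'
#' @param trace A `stressci_pulse`.
#' @param path CSV output path.
#' @return The path, invisibly.
#' @export
write_pulse_csv <- function(trace, path) {
  stopifnot(inherits(trace, "stressci_pulse"))
  readr::write_csv(tibble(time_s = trace$time, value = trace$values), path)
  jsonlite::write_json(
    list(sample_rate = trace$sample_rate, true_beat_times = trace$true_beat_times),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a pulse trace written by [write_pulse_csv()]
#'
#' @param path CSV path (sidecar `<path>.json` is read when present).
#' @param sample_rate Sample rate override when no sidecar exists.
#' @return A `stressci_pulse`.
#' @export
read_pulse_csv <- function(path, sample_rate = NULL) {
  d <- readr::read_csv(path, col_types = "dd")
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  sr <- meta$sample_rate %||% sample_rate %||% (1 / stats::median(diff(d$time_s)))
  structure(
    list(
      sample_rate = sr, time = d$time_s, values = d$value,
      true_beat_times = meta$true_beat_times %||% numeric(0), hr = NA_real_
    ),
    class = "stressci_pulse"
  )
}
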