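#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_hline geom_vline
#'   labs theme_minimal autoplot facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a pulse trace with detected and true beats
#'
#' @param object A `stressci_pulse`.
#' @param beats Optional beat times (seconds) to mark.
#' @param window Time window (seconds) to display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stressci_pulse <- function(object, beats = NULL, window = c(0, 10), ...) {
  d <- tibble(time = object$time, value = object$values)
  d <- d[d$time >= window[1] & d$time <= window[2], ]
  p <- ggplot(d, aes(.data$time, .data$value)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (s)", y = "signal (a.u.)", title = "Pulse waveform") +
    theme_minimal()
  tb <- object$true_beat_times
  tb <- tb[tb >= window[1] & tb <= window[2]]
  if (length(tb)) {
    p <- p + geom_vline(xintercept = tb, colour = "grey70", linetype = 3)
  }
  if (!is.null(beats)) {
    beats <- beats[beats >= window[1] & beats <= window[2]]
    p <- p + geom_vline(xintercept = beats, colour = "red", linetype = 2, alpha = 0.6)
  }
  p
}

#' Plot a fitted baseline over the observed series
#'
#' @param object A `stressci_baseline`.
#' @param series Optional observed data frame (`time`, `value`) to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stressci_baseline <- function(object, series = NULL, ...) {
  grid <- tibble(
    time = seq(object$window[1], object$window[2], length.out = 200)
  )
  grid$value <- predict_baseline(object, grid$time)
  p <- ggplot(grid, aes(.data$time, .data$value)) +
    geom_line(colour = "steelblue") +
    geom_vline(xintercept = object$benchmark_time, linetype = 3) +
    labs(
      x = "clock time (h)", y = object$biomarker %||% "baseline",
      title = sprintf("Fitted %s baseline", object$family)
    ) +
    theme_minimal()
  if (!is.null(series)) {
    p <- p + geom_point(data = as_tibble(series), aes(.data$time, .data$value))
  }
  p
}

#' Plot a composite stress index stream with the warning threshold
#'
#' @param ssci1_stream Index values in time order.
#' @param times Time stamps (defaults to the index positions).
#' @param reference_max Reference maximum for the warning rule.
#' @param fraction Warning fraction (default 0.8).
#' @return A ggplot with the threshold and any trigger marked.
#' @export
plot_ssci_stream <- function(ssci1_stream, times = seq_along(ssci1_stream),
                             reference_max = max(ssci1_stream), fraction = 0.8) {
  d <- tibble(time = times, ssci1 = ssci1_stream)
  trig <- warning_trigger(ssci1_stream, reference_max, fraction, times = times)
  p <- ggplot(d, aes(.data$time, .data$ssci1)) +
    geom_line() +
    geom_hline(yintercept = fraction * reference_max, linetype = 2, colour = "red") +
    labs(x = "time", y = "composite index", title = "Stress index stream") +
    theme_minimal()
  if (trig$triggered) {
    p <- p + geom_vline(xintercept = d$time[trig$index], colour = "red", alpha = 0.5)
  }
  p
}

#' Plot ROC or precision-recall curves of the classifier suite
#'
#' @param object A `stressci_eval` from [evaluate_classifiers()].
#' @param type `"roc"` or `"pr"`.
#' @param ... Unused.
#' @return A ggplot with one panel per algorithm.
#' @export
autoplot.stressci_eval <- function(object, type = c("roc", "pr"), ...) {
  type <- match.arg(type)
  if (type == "roc") {
    d <- purrr::imap_dfr(object$per_algorithm, function(r, alg) {
      dplyr::mutate(r$roc_curve, algorithm = alg)
    })
    ggplot(d, aes(.data$fpr, .data$tpr, colour = .data$algorithm)) +
      geom_line() +
      labs(x = "false positive rate", y = "true positive rate", title = "ROC") +
      theme_minimal()
  } else {
    d <- purrr::imap_dfr(object$per_algorithm, function(r, alg) {
      dplyr::mutate(r$pr_curve, algorithm = alg)
    })
    ggplot(d, aes(.data$recall, .data$precision, colour = .data$algorithm)) +
      geom_line() +
      labs(x = "recall", y = "precision", title = "Precision-recall") +
      theme_minimal()
  }
}
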