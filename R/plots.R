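#' Plot an averaged ERP waveform
#'
#' @param object An `erp_wave` from [compute_erp()].
#' @param window_ms Optional shaded search window.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.erp_wave <- function(object, window_ms = c(300, 600), ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ms,
                                            y = .data$amp_uv)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey70") +
    ggplot2::geom_vline(xintercept = 0, color = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (ms)", y = expression("Amplitude (" * mu * "V)"),
                  title = sprintf("ERP at %s (%d trials)",
                                  attr(object, "channel") %||% "",
                                  attr(object, "n_trials") %||% NA)) +
    ggplot2::theme_minimal()
  if (!is.null(window_ms)) {
    p <- p + ggplot2::annotate("rect", xmin = window_ms[1],
                               xmax = window_ms[2], ymin = -Inf, ymax = Inf,
                               alpha = 0.1, fill = "steelblue")
  }
  p
}

#' Plot an ERSP map
#'
#' @param object An `ersp_map`.
#' @param mark Optional one-row tibble from [ersp_window_max()] whose
#'   (time, frequency) location is marked with a cross.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ersp_map <- function(object, mark = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms,
                                        y = .data$freq_hz,
                                        fill = .data$power_db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", name = "dB") +
    ggplot2::labs(x = "Time (ms)", y = "Frequency (Hz)",
                  title = sprintf("ERSP at %s (%d trials)", object$channel,
                                  object$n_trials)) +
    ggplot2::theme_minimal()
  if (!is.null(mark)) {
    p <- p + ggplot2::annotate("point", x = mark$time_ms, y = mark$freq_hz,
                               shape = 4, size = 4, stroke = 1.5,
                               color = "white")
  }
  p
}

#' @export
tidy.ersp_map <- function(x, ...) {
  tibble(
    freq_hz = rep(x$freqs_hz, times = length(x$times_ms)),
    time_ms = rep(x$times_ms, each = length(x$freqs_hz)),
    power_db = as.vector(x$values)
  )
}

#' Plot the stimulation or sham waveform
#'
#' @param params A `stim_params`.
#' @param rate_hz Sampling rate of the drawn waveform.
#' @param zoom_s Optional length-2 time window in seconds.
#' @return A ggplot.
#' @export
plot_stim_waveform <- function(params, rate_hz = 200, zoom_s = NULL) {
  wf <- generate_waveform(params, rate_hz)
  if (!is.null(zoom_s)) {
    wf <- wf[wf$time_s >= zoom_s[1] & wf$time_s <= zoom_s[2], ]
  }
  ggplot2::ggplot(wf, ggplot2::aes(x = .data$time_s,
                                   y = .data$current_ma)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "Time (s)", y = "Current (mA)",
                  title = sprintf("%s waveform, %g Hz, %g mA peak-to-peak",
                                  params$mode, params$stim_freq_hz,
                                  params$amplitude_ma)) +
    ggplot2::theme_minimal()
}

#' Plot group change scores of a finished study
#'
#' @param study An `oddlock_study`.
#' @param measure Measure to plot (default `"p3_amp_uv"`).
#' @param comparison Comparison to plot (default `"pre-to-post"`).
#' @return A ggplot.
#' @export
plot_change_scores <- function(study, measure = "p3_amp_uv",
                               comparison = "pre-to-post") {
  df <- study$changes[study$changes$measure == measure &
                        study$changes$comparison == comparison, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value,
                                   color = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1) +
    ggplot2::labs(x = NULL, y = sprintf("%s change (%s)", measure,
                                        df$basis[1]),
                  title = sprintf("%s, %s", measure, comparison)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
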