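#' Construct a continuous EEG recording
#'
#' The in-memory container for continuous multichannel EEG: a channels x
#' samples matrix in microvolts plus an event table. Sample indices are
#' 1-based (R convention); all latencies reported downstream are in
#' milliseconds relative to stimulus onset.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param channel_labels Character vector of unique channel labels (10-10
#'   names), one per row of `data`.
#' @param events Tibble/data frame with columns `sample` (1-based integer
#'   index into the recording) and `code` (character, e.g. `"standard"`,
#'   `"target"`, `"response"`, `"tacs_zero_cross"`). May be empty.
#' @param reference Reference description, a channel label or `"average"`.
#'
#' @return An object of class `eeg_recording`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2000), nrow = 2), 1000, c("Pz", "Cz"))
#' rec
eeg_recording <- function(data, sampling_rate_hz, channel_labels,
                          events = empty_events(), reference = "none") {
  data <- as.matrix(data)
  if (!is.numeric(data)) {
    abort("`data` must be a numeric channels x samples matrix.",
          class = "oddlock_parameter_error")
  }
  check_scalar(sampling_rate_hz, "sampling_rate_hz", min = 0,
               strict_min = TRUE)
  if (length(channel_labels) != nrow(data) ||
      anyDuplicated(channel_labels)) {
    abort("`channel_labels` must be unique, one per data row.",
          class = "oddlock_parameter_error")
  }
  events <- as_tibble(events)
  if (nrow(events) > 0) {
    if (!all(c("sample", "code") %in% names(events))) {
      abort("`events` needs columns `sample` and `code`.",
            class = "oddlock_parameter_error")
    }
    if (any(events$sample < 1L) || any(events$sample > ncol(data))) {
      abort("Event sample indices fall outside the recording.",
            class = "oddlock_parameter_error")
    }
    events <- events[order(events$sample), , drop = FALSE]
  }
  rownames(data) <- channel_labels
  structure(list(
    data = data,
    sampling_rate_hz = sampling_rate_hz,
    channel_labels = as.character(channel_labels),
    events = events,
    reference = reference
  ), class = "eeg_recording")
}

#' @export
#' @rdname eeg_recording
empty_events <- function() {
  tibble(sample = integer(), code = character())
}

#' @export
print.eeg_recording <- function(x, ...) {
  dur <- ncol(x$data) / x$sampling_rate_hz
  cat("<eeg_recording>\n")
  cat(sprintf("  %d channels x %d samples (%.1f s @ %g Hz), reference: %s\n",
              nrow(x$data), ncol(x$data), dur, x$sampling_rate_hz,
              x$reference))
  if (nrow(x$events)) {
    tab <- table(x$events$code)
    cat("  events:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  } else {
    cat("  events: none\n")
  }
  invisible(x)
}

# internal: samples <-> milliseconds (sample 1 is time 0)
ms_to_samples <- function(ms, sfreq) as.integer(round(ms * sfreq / 1000))
samples_to_ms <- function(s, sfreq) (s - 1) * 1000 / sfreq
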