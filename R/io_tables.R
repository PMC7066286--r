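#' Read or write a recording in a standard EEG format
#'
#' Thin dispatchers over [write_brainvision()]/[read_brainvision()] and
#' [write_edf()]/[read_edf()]. `format = "auto"` infers the format from the
#' file extension (`.vhdr` / `.edf`).
#'
#' @param rec An [eeg_recording()].
#' @param path Target path: a `.vhdr`/`.edf` file (or a stem for
#'   BrainVision).
#' @param format `"edf"`, `"brainvision"` or `"auto"`.
#' @return `write_recording()` returns the written header path;
#'   `read_recording()` returns an [eeg_recording()].
#' @export
write_recording <- function(rec, path, format = c("auto", "edf",
                                                  "brainvision")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else
      "brainvision"
  }
  if (format == "edf") {
    write_edf(rec, path)
  } else {
    stem <- sub("\\.vhdr$", "", path, ignore.case = TRUE)
    write_brainvision(rec, stem)
    paste0(stem, ".vhdr")
  }
}

#' @rdname write_recording
#' @export
read_recording <- function(path, format = c("auto", "edf", "brainvision")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
    else if (grepl("\\.vhdr$", path, ignore.case = TRUE)) "brainvision"
    else abort(sprintf("Cannot infer format of `%s`.", path),
               class = "oddlock_format_error")
  }
  if (format == "edf") read_edf(path) else read_brainvision(path)
}

#' Write the event stream as a tab-separated table
#'
#' Columns: `onset_s`, `duration_s`, `trial_type`, `response_time_s`
#' (response latency for responded stimulus events, `NA` otherwise).
#'
#' @param schedule A `trial_schedule`.
#' @param behavior A `behavior_table` aligned to it (optional).
#' @param path Output `.tsv` path.
#' @param stim_duration_ms Stimulus duration for the `duration_s` column.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(schedule, behavior = NULL, path,
                              stim_duration_ms = 1000) {
  rt <- rep(NA_real_, nrow(schedule))
  if (!is.null(behavior)) {
    rt <- behavior$rt_ms[match(schedule$trial, behavior$trial)] / 1000
  }
  df <- tibble(
    onset_s = schedule$onset_ms / 1000,
    duration_s = stim_duration_ms / 1000,
    trial_type = schedule$stimulus_type,
    response_time_s = rt
  )
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Serialize stimulation parameters as JSON
#'
#' Keys: `p3_latency_ms`, `stim_freq_hz`, `wait_ms`, `amplitude_ma`,
#' `ramp_s`, `duration_s`, `mode`.
#'
#' @param params A `stim_params`.
#' @param path Output `.json` path.
#' @return `path` invisibly; `read_stim_params()` returns a `stim_params`.
#' @export
write_stim_params <- function(params, path) {
  jsonlite::write_json(
    params[c("p3_latency_ms", "stim_freq_hz", "wait_ms", "amplitude_ma",
             "ramp_s", "duration_s", "mode")],
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stim_params
#' @export
read_stim_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stim_params(p3_latency_ms = x$p3_latency_ms,
              stim_freq_hz = x$stim_freq_hz,
              wait_ms = x$wait_ms,
              amplitude_ma = x$amplitude_ma,
              ramp_s = x$ramp_s,
              duration_s = x$duration_s,
              mode = x$mode)
}

#' Outcome and change tables as CSV
#'
#' @param x An `outcome_set` (or change table).
#' @param path Output `.csv` path.
#' @return `path` invisibly; the reader returns a tibble.
#' @export
write_outcomes_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_outcomes_csv
#' @export
read_outcomes_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
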