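#' Preprocessing presets
#'
#' Two named chains are used throughout: the `online` chain applied between
#' the pre block and stimulation (high-pass 0.5 Hz, low-pass 20 Hz, epochs
#' -3 to 4 s, baseline -50 to 0 ms, blink-trial rejection on) and the
#' `offline` chain used for outcome extraction (additionally low-pass 8 Hz,
#' average reference, ICA blink cleanup).
#'
#' @param preset `"online"` or `"offline"`.
#' @return A named list of chain parameters.
#' @export
#' @examples
#' preprocess_preset("online")$low_pass_hz
preprocess_preset <- function(preset = c("online", "offline")) {
  preset <- match.arg(preset)
  common <- list(
    preset = preset,
    window_ms = c(-3000, 4000),
    baseline_ms = c(-50, 0),
    reject = list(threshold_uv = 100, uniformity_r = 0.8,
                  window_ms = c(0, 1000))
  )
  if (preset == "online") {
    modifyList(common, list(high_pass_hz = 0.5, low_pass_hz = 20,
                            average_reference = FALSE, ica = FALSE))
  } else {
    modifyList(common, list(high_pass_hz = 0.5, low_pass_hz = 8,
                            average_reference = TRUE, ica = TRUE))
  }
}

# internal: zero-phase Butterworth filtering of one signal matrix
# (channels x samples). Forward-backward application of signal::butter
# coefficients with reflection padding so edge transients stay out of the
# record. Order is per pass; the double pass squares the magnitude response.
zero_phase_filter <- function(x, sfreq, type, cutoff_hz, order = 4) {
  bf <- signal::butter(order, 2 * cutoff_hz / sfreq, type = type)
  n <- ncol(x)
  pad <- min(n - 1L, as.integer(ceiling(3 * sfreq / cutoff_hz)))
  out <- x
  for (ci in seq_len(nrow(x))) {
    s <- x[ci, ]
    # odd reflection keeps the signal continuous at the joints
    ext <- c(2 * s[1] - s[(pad + 1):2], s, 2 * s[n] - s[(n - 1):(n - pad)])
    f1 <- signal::filter(bf, ext)
    f2 <- rev(signal::filter(bf, rev(f1)))
    out[ci, ] <- f2[(pad + 1):(pad + n)]
  }
  out
}

#' Zero-phase band filtering of a recording
#'
#' Applies forward-backward (zero-phase) Butterworth filters, so peak
#' latencies are not shifted by group delay: the latency that drives
#' stimulation timing must not be biased by the filter. Passband gain error
#' is below 1% and attenuation at twice a low-pass cutoff exceeds 20 dB.
#'
#' @param rec An [eeg_recording()].
#' @param high_pass_hz High-pass cutoff in Hz, or `NULL` to skip.
#' @param low_pass_hz Low-pass cutoff in Hz, or `NULL` to skip.
#' @param order Butterworth order per pass (default 4).
#'
#' @return The filtered [eeg_recording()].
#' @export
filter_signal <- function(rec, high_pass_hz = NULL, low_pass_hz = NULL,
                          order = 4) {
  nyq <- rec$sampling_rate_hz / 2
  for (co in c(high_pass_hz, low_pass_hz)) {
    if (co <= 0 || co >= nyq) {
      abort(sprintf("Cutoff %g Hz outside (0, Nyquist = %g).", co, nyq),
            class = "oddlock_parameter_error")
    }
  }
  if (!is.null(high_pass_hz) && !is.null(low_pass_hz) &&
      high_pass_hz >= low_pass_hz) {
    abort("`high_pass_hz` must be below `low_pass_hz`.",
          class = "oddlock_parameter_error")
  }
  x <- rec$data
  if (!is.null(high_pass_hz)) {
    x <- zero_phase_filter(x, rec$sampling_rate_hz, "high", high_pass_hz,
                           order)
  }
  if (!is.null(low_pass_hz)) {
    x <- zero_phase_filter(x, rec$sampling_rate_hz, "low", low_pass_hz,
                           order)
  }
  rec$data <- x
  rec
}

#' Cut stimulus-locked epochs out of a recording
#'
#' One epoch per event of the requested codes, on a closed millisecond window
#' (the default -3000 to 4000 ms window at 1000 Hz gives 7001 samples).
#' The per-channel mean over the baseline window is subtracted from each
#' epoch. Events whose window would run past either record edge are dropped
#' and counted.
#'
#' @param rec An [eeg_recording()].
#' @param window_ms Length-2 epoch window in ms relative to the event.
#' @param baseline_ms Length-2 baseline window in ms (must lie inside
#'   `window_ms`); `NULL` skips baseline correction.
#' @param codes Event codes to epoch around.
#'
#' @return An object of class `epoch_set`: trials x channels x time array
#'   (`$data`), time axis in ms (`$times`), channel labels, and a `$trials`
#'   tibble (`trial`, `event_sample`, `stimulus_type`, `rejected`,
#'   `rejection_reason`).
#' @export
epoch_recording <- function(rec, window_ms = c(-3000, 4000),
                            baseline_ms = c(-50, 0),
                            codes = c("standard", "target")) {
  if (!is.null(baseline_ms) &&
      (baseline_ms[1] < window_ms[1] || baseline_ms[2] > window_ms[2])) {
    abort("`baseline_ms` must lie inside `window_ms`.",
          class = "oddlock_parameter_error")
  }
  sfreq <- rec$sampling_rate_hz
  ev <- rec$events[rec$events$code %in% codes, , drop = FALSE]
  if (nrow(ev) == 0) {
    abort(sprintf("No events with code(s) %s in the recording.",
                  paste(codes, collapse = ", ")),
          class = "oddlock_empty_set_error")
  }
  rel <- ms_to_samples(window_ms[1], sfreq):ms_to_samples(window_ms[2], sfreq)
  times <- rel * 1000 / sfreq
  n_samp <- ncol(rec$data)
  ok <- ev$sample + rel[1] >= 1L & ev$sample + rel[length(rel)] <= n_samp
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    inform(sprintf("Dropped %d event(s) too close to the record edges.",
                   n_dropped))
  }
  ev <- ev[ok, , drop = FALSE]
  if (nrow(ev) == 0) {
    abort("All matching events fall too close to the record edges.",
          class = "oddlock_empty_set_error")
  }
  n_tr <- nrow(ev)
  n_ch <- nrow(rec$data)
  arr <- array(NA_real_, dim = c(n_tr, n_ch, length(rel)),
               dimnames = list(NULL, rec$channel_labels, NULL))
  for (k in seq_len(n_tr)) {
    arr[k, , ] <- rec$data[, ev$sample[k] + rel, drop = FALSE]
  }
  if (!is.null(baseline_ms)) {
    bidx <- which(times >= baseline_ms[1] & times <= baseline_ms[2])
    bl <- apply(arr[, , bidx, drop = FALSE], c(1, 2), mean)
    arr <- arr - array(bl, dim = dim(arr))
  }
  structure(list(
    data = arr,
    times = times,
    channels = rec$channel_labels,
    sampling_rate_hz = sfreq,
    baseline_ms = baseline_ms,
    reference = rec$reference,
    n_dropped_edge = n_dropped,
    trials = tibble(
      trial = seq_len(n_tr),
      event_sample = ev$sample,
      stimulus_type = ev$code,
      rejected = FALSE,
      rejection_reason = NA_character_
    )
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set>\n")
  cat(sprintf("  %d trials x %d channels x %d samples (%g..%g ms @ %g Hz)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times), max(x$times), x$sampling_rate_hz))
  cat(sprintf("  types: %s; rejected: %d\n",
              paste(sprintf("%s=%d", names(table(x$trials$stimulus_type)),
                            as.integer(table(x$trials$stimulus_type))),
                    collapse = ", "),
              sum(x$trials$rejected)))
  invisible(x)
}

# internal: indices of retained (non-rejected) trials, optionally of one type
retained_trials <- function(ep, stimulus_type = NULL) {
  keep <- !ep$trials$rejected
  if (!is.null(stimulus_type)) {
    keep <- keep & ep$trials$stimulus_type %in% stimulus_type
  }
  which(keep)
}

#' Reject blink-contaminated trials
#'
#' A trial is rejected when, within the inspection window, (a) the absolute
#' amplitude exceeds `amp_threshold_uv` on at least one channel and (b) the
#' median pairwise inter-channel correlation of the window exceeds
#' `uniformity_r` — the operational form of "a large deflection, uniform on
#' all channels". Retained trials are untouched; reasons are recorded in the
#' trial table.
#'
#' @param ep An `epoch_set`.
#' @param amp_threshold_uv Amplitude threshold in microvolts (default 100).
#' @param uniformity_r Median pairwise correlation threshold (default 0.8).
#' @param window_ms Inspection window in ms post-onset (default 0-1000).
#'
#' @return The `epoch_set` with updated rejection flags.
#' @export
reject_blink_trials <- function(ep, amp_threshold_uv = 100,
                                uniformity_r = 0.8,
                                window_ms = c(0, 1000)) {
  if (window_ms[1] < min(ep$times) || window_ms[2] > max(ep$times)) {
    abort("`window_ms` must lie inside the epoch window.",
          class = "oddlock_parameter_error")
  }
  idx <- which(ep$times >= window_ms[1] & ep$times <= window_ms[2])
  for (k in seq_len(dim(ep$data)[1])) {
    if (ep$trials$rejected[k]) next
    w <- ep$data[k, , idx]
    if (max(abs(w)) <= amp_threshold_uv) next
    r <- suppressWarnings(cor(t(w)))
    med_r <- median(r[upper.tri(r)], na.rm = TRUE)
    if (!is.na(med_r) && med_r > uniformity_r) {
      ep$trials$rejected[k] <- TRUE
      ep$trials$rejection_reason[k] <- "blink"
    }
  }
  ep
}

#' Re-reference epochs to the common average
#'
#' Subtracts, at each trial and sample, the mean across channels, so the
#' channel mean is numerically zero everywhere. Inter-channel differences are
#' preserved exactly; the operation is idempotent.
#'
#' @param ep An `epoch_set` with at least two channels.
#' @return The re-referenced `epoch_set` (`$reference == "average"`).
#' @export
average_reference <- function(ep) {
  if (dim(ep$data)[2] < 2) {
    abort("Average reference needs at least two channels.",
          class = "oddlock_parameter_error")
  }
  m <- apply(ep$data, c(1, 3), mean)          # trials x time
  ep$data <- ep$data - aperm(
    array(m, dim = c(dim(ep$data)[1], dim(ep$data)[3], dim(ep$data)[2])),
    c(1, 3, 2))
  ep$reference <- "average"
  ep
}
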