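#' Time-frequency analysis presets
#'
#' The `online` grid (used between pre block and stimulation): 1.5-20 Hz in
#' 0.5 Hz steps, 3-cycle wavelets, 24 ms time resolution. The `offline` grid
#' (outcome extraction): 0.8-10 Hz in 0.25 Hz steps, 14 ms time resolution.
#' The baseline is the -3 to 0 s pre-stimulus interval in both.
#'
#' @param preset `"online"` or `"offline"`.
#' @return Named list of grid parameters.
#' @export
tfr_preset <- function(preset = c("online", "offline")) {
  preset <- match.arg(preset)
  if (preset == "online") {
    list(freq_range_hz = c(1.5, 20), freq_step_hz = 0.5, n_cycles = 3,
         time_step_ms = 24, baseline_ms = c(-3000, 0))
  } else {
    list(freq_range_hz = c(0.8, 10), freq_step_hz = 0.25, n_cycles = 3,
         time_step_ms = 14, baseline_ms = c(-3000, 0))
  }
}

#' Morlet-wavelet event-related spectral perturbation
#'
#' Computes, per retained trial of the requested condition, the complex
#' Morlet transform of one channel (constant `n_cycles` across frequencies,
#' implemented as a Gaussian frequency-domain window of SD `f / n_cycles`
#' around each analysis frequency), averages power over trials, and expresses
#' it in dB relative to the per-frequency mean baseline power:
#' `10 * log10(P(f, t) / mean P(f, t in baseline))`. The map is sampled on
#' the requested time grid. Cells closer to an epoch edge than three wavelet
#' SDs are marked invalid (`NA`) and excluded from maxima.
#'
#' @param ep An `epoch_set`.
#' @param channel Channel label to analyze (typically `"Pz"`).
#' @param freq_range_hz Length-2 frequency range in Hz.
#' @param freq_step_hz Frequency resolution in Hz.
#' @param n_cycles Wavelet cycles, constant across frequencies.
#' @param time_step_ms Time resolution of the output grid in ms.
#' @param baseline_ms Length-2 baseline window in ms (before 0).
#' @param stimulus_type Condition to average (default `"target"`).
#' @param decim Integer subsampling factor applied to the epoch time axis
#'   before the transform (safe once the signal is low-pass filtered well
#'   below the decimated Nyquist; the online chain's 20 Hz low-pass allows
#'   `decim = 4` at 1000 Hz).
#'
#' @return An object of class `ersp_map`: `$values` (freqs x times, dB, `NA`
#'   where invalid), `$freqs_hz`, `$times_ms`, plus grid metadata.
#' @export
wavelet_ersp <- function(ep, channel = "Pz",
                         freq_range_hz = c(1.5, 20), freq_step_hz = 0.5,
                         n_cycles = 3, time_step_ms = 24,
                         baseline_ms = c(-3000, 0),
                         stimulus_type = "target", decim = 1L) {
  if (!channel %in% ep$channels) {
    abort(sprintf("Channel `%s` not present.", channel),
          class = "oddlock_parameter_error")
  }
  sfreq <- ep$sampling_rate_hz / decim
  if (freq_range_hz[2] >= sfreq / 2) {
    abort("Frequency range exceeds the (decimated) Nyquist frequency.",
          class = "oddlock_parameter_error")
  }
  if (baseline_ms[1] < min(ep$times) || baseline_ms[2] > max(ep$times)) {
    abort("Baseline window outside the epoch.",
          class = "oddlock_parameter_error")
  }
  keep <- retained_trials(ep, stimulus_type)
  if (length(keep) == 0) {
    abort("No retained trials of the requested condition.",
          class = "oddlock_empty_set_error")
  }
  tidx <- seq(1L, length(ep$times), by = as.integer(decim))
  times <- ep$times[tidx]
  x <- t(ep$data[keep, match(channel, ep$channels), tidx, drop = TRUE])
  if (length(keep) == 1L) x <- matrix(ep$data[keep, match(channel, ep$channels), tidx], ncol = 1)
  n_t <- nrow(x)
  n_tr <- ncol(x)
  nfft <- stats::nextn(n_t, 2)
  xp <- rbind(x, matrix(0, nfft - n_t, n_tr))
  spec <- stats::mvfft(xp)
  fbins <- (seq_len(nfft) - 1) * sfreq / nfft          # 0 .. sfreq
  freqs <- seq(freq_range_hz[1], freq_range_hz[2], by = freq_step_hz)
  power <- matrix(0, length(freqs), n_t)
  for (fi in seq_along(freqs)) {
    f0 <- freqs[fi]
    sigma_f <- f0 / n_cycles
    # analytic-signal Gaussian window on positive frequencies only
    win <- 2 * exp(-(fbins - f0)^2 / (2 * sigma_f^2))
    win[fbins > sfreq / 2] <- 0
    an <- stats::mvfft(spec * win, inverse = TRUE) / nfft
    power[fi, ] <- rowMeans(Mod(an[seq_len(n_t), , drop = FALSE])^2)
  }
  # invalidate edge cells: within 3 wavelet temporal SDs of either epoch edge
  sigma_t_ms <- 1000 * n_cycles / (2 * pi * freqs)
  for (fi in seq_along(freqs)) {
    bad <- times < times[1] + 3 * sigma_t_ms[fi] |
      times > times[n_t] - 3 * sigma_t_ms[fi]
    power[fi, bad] <- NA_real_
  }
  bidx <- which(times >= baseline_ms[1] & times <= baseline_ms[2])
  base <- rowMeans(power[, bidx, drop = FALSE], na.rm = TRUE)
  vals <- 10 * log10(power / base)
  # resample onto the requested time grid (nearest sample)
  grid <- seq(min(ep$times), max(ep$times), by = time_step_ms)
  gidx <- vapply(grid, function(g) which.min(abs(times - g)), integer(1))
  structure(list(
    values = vals[, gidx, drop = FALSE],
    freqs_hz = freqs,
    times_ms = times[gidx],
    baseline_ms = baseline_ms,
    n_cycles = n_cycles,
    channel = channel,
    n_trials = n_tr
  ), class = "ersp_map")
}

#' @export
print.ersp_map <- function(x, ...) {
  cat("<ersp_map>\n")
  cat(sprintf("  %s, %d trials: %g-%g Hz (step %g), %g..%g ms, %d-cycle wavelets\n",
              x$channel, x$n_trials, min(x$freqs_hz), max(x$freqs_hz),
              diff(x$freqs_hz[1:2]), min(x$times_ms), max(x$times_ms),
              x$n_cycles))
  invisible(x)
}

#' Windowed maximum of an ERSP map
#'
#' Global maximum over the cells inside `center_time_ms +/-
#' time_halfwidth_ms` and, when a center frequency is given,
#' `center_freq_hz +/- freq_halfwidth_hz` (otherwise the whole frequency
#' axis — the online stimulation-frequency case). Ties are broken toward the
#' earliest time, then the lowest frequency. Windows are clipped to the map
#' with a flag.
#'
#' @param m An `ersp_map`.
#' @param center_time_ms,time_halfwidth_ms Time window center and halfwidth.
#' @param center_freq_hz,freq_halfwidth_hz Frequency window; both `NULL` for
#'   the full axis.
#'
#' @return One-row tibble: `value_db`, `time_ms`, `freq_hz`, `clipped`.
#' @export
ersp_window_max <- function(m, center_time_ms, time_halfwidth_ms = 150,
                            center_freq_hz = NULL, freq_halfwidth_hz = NULL) {
  tin <- m$times_ms >= center_time_ms - time_halfwidth_ms &
    m$times_ms <= center_time_ms + time_halfwidth_ms
  if (is.null(center_freq_hz)) {
    fin <- rep(TRUE, length(m$freqs_hz))
  } else {
    fin <- m$freqs_hz >= center_freq_hz - freq_halfwidth_hz &
      m$freqs_hz <= center_freq_hz + freq_halfwidth_hz
  }
  clipped <- (center_time_ms - time_halfwidth_ms < min(m$times_ms)) ||
    (center_time_ms + time_halfwidth_ms > max(m$times_ms)) ||
    (!is.null(center_freq_hz) &&
       (center_freq_hz - freq_halfwidth_hz < min(m$freqs_hz) ||
          center_freq_hz + freq_halfwidth_hz > max(m$freqs_hz)))
  sub <- m$values[fin, tin, drop = FALSE]
  if (length(sub) == 0 || all(is.na(sub))) {
    abort("Window does not intersect any valid map cell.",
          class = "oddlock_parameter_error")
  }
  best <- max(sub, na.rm = TRUE)
  hits <- which(sub == best, arr.ind = TRUE)
  t_sub <- m$times_ms[tin]
  f_sub <- m$freqs_hz[fin]
  # earliest time first, then lowest frequency
  ord <- order(t_sub[hits[, 2]], f_sub[hits[, 1]])
  pick <- hits[ord[1], ]
  tibble(value_db = best, time_ms = t_sub[pick[2]], freq_hz = f_sub[pick[1]],
         clipped = clipped)
}

#' Export an ERSP map as a plain matrix CSV
#'
#' First row holds the time axis (ms), first column the frequency axis (Hz).
#'
#' @param m An `ersp_map`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ersp_csv <- function(m, path) {
  df <- as.data.frame(cbind(freq_hz = m$freqs_hz, m$values))
  names(df) <- c("freq_hz", as.character(m$times_ms))
  readr::write_csv(df, path)
  invisible(path)
}
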