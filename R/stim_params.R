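#' Average ERP at one channel
#'
#' Stimulus-locked average over retained trials of the requested condition.
#'
#' @param ep An `epoch_set`.
#' @param channel Channel label (default `"Pz"`).
#' @param stimulus_type Condition to average (default `"target"`).
#' @return A tibble of class `erp_wave` with `time_ms`, `amp_uv`, and the
#'   trial count as attribute `n_trials`.
#' @export
compute_erp <- function(ep, channel = "Pz", stimulus_type = "target") {
  if (!channel %in% ep$channels) {
    abort(sprintf("Channel `%s` not present.", channel),
          class = "oddlock_parameter_error")
  }
  keep <- retained_trials(ep, stimulus_type)
  if (length(keep) == 0) {
    abort("No retained trials of the requested condition.",
          class = "oddlock_empty_set_error")
  }
  ci <- match(channel, ep$channels)
  amp <- if (length(keep) == 1L) ep$data[keep, ci, ] else
    colMeans(ep$data[keep, ci, , drop = TRUE])
  out <- tibble(time_ms = ep$times, amp_uv = amp)
  attr(out, "n_trials") <- length(keep)
  attr(out, "channel") <- channel
  class(out) <- c("erp_wave", class(out))
  out
}

#' Estimate P300 peak latency from an ERP
#'
#' Time of the maximum sample of the averaged ERP inside the closed search
#' window (default 300-600 ms, the corrected estimation window; `c(0, 900)`
#' reproduces the initial wide window). Ties go to the earliest time; a
#' maximum sitting on a window boundary is flagged.
#'
#' @param erp An `erp_wave` (or any data frame with `time_ms`, `amp_uv`).
#' @param window_ms Closed search window in ms.
#' @return A list: `latency_ms`, `amp_uv`, `at_boundary`.
#' @export
#' @examples
#' erp <- tibble::tibble(time_ms = 0:900,
#'                       amp_uv = exp(-(0:900 - 440)^2 / 2e4))
#' estimate_p300_latency(erp)$latency_ms
estimate_p300_latency <- function(erp, window_ms = c(300, 600)) {
  if (window_ms[1] < min(erp$time_ms) || window_ms[2] > max(erp$time_ms)) {
    abort("Search window outside the ERP support.",
          class = "oddlock_parameter_error")
  }
  idx <- which(erp$time_ms >= window_ms[1] & erp$time_ms <= window_ms[2])
  k <- idx[which.max(erp$amp_uv[idx])]       # which.max: earliest tie wins
  lat <- erp$time_ms[k]
  list(latency_ms = lat,
       amp_uv = erp$amp_uv[k],
       at_boundary = k == idx[1] || k == idx[length(idx)])
}

#' Estimate the individual stimulation frequency
#'
#' The frequency at the ERSP maximum within +/-150 ms around the individual
#' P300 latency, over the full frequency axis of the map.
#'
#' @param m An `ersp_map`.
#' @param p3_latency_ms Individual P300 latency in ms.
#' @param time_halfwidth_ms Halfwidth of the search window (default 150 ms).
#' @return Frequency in Hz.
#' @export
estimate_stim_frequency <- function(m, p3_latency_ms,
                                    time_halfwidth_ms = 150) {
  ersp_window_max(m, center_time_ms = p3_latency_ms,
                  time_halfwidth_ms = time_halfwidth_ms)$freq_hz
}

#' Wait duration aligning the P300 peak with a stimulation peak
#'
#' The stimulation waveform is `sin(2 * pi * f * t)` started at a rising
#' zero-crossing (`t = 0` at the trigger), so peaks fall at `T/4 + k * T`
#' with `T = 1000 / f` ms. Presenting the stimulus `wait` ms after the
#' trigger puts the P300 peak (latency `L` after stimulus onset) on a
#' stimulation peak when `wait = (T/4 - L) mod T`, the shortest non-negative
#' wait.
#'
#' @param p3_latency_ms P300 latency `L` in ms.
#' @param stim_freq_hz Stimulation frequency `f` in Hz.
#' @return Wait duration in ms, in `[0, T)`.
#' @export
#' @examples
#' compute_wait(0, 1)          # quarter period: 250 ms
#' compute_wait(440, 2.5)      # 60 ms
compute_wait <- function(p3_latency_ms, stim_freq_hz) {
  check_scalar(stim_freq_hz, "stim_freq_hz", min = 0, strict_min = TRUE)
  period <- 1000 / stim_freq_hz
  (period / 4 - p3_latency_ms) %% period
}

#' Phase of the stimulation sinusoid at a given post-onset latency
#'
#' With the stimulus presented `wait` ms after a rising zero-crossing
#' trigger, the stimulation phase at `latency` ms post-onset is
#' `2 * pi * f * (wait + latency) / 1000, mod 2 * pi`. When
#' `wait = compute_wait(latency, f)` this is exactly `pi / 2` (a peak).
#'
#' @param latency_ms Latency after stimulus onset, ms.
#' @param freq_hz Stimulation frequency, Hz.
#' @param wait_ms Wait duration, ms.
#' @return Phase in radians, in `[0, 2 * pi)`.
#' @export
stimulation_phase_at <- function(latency_ms, freq_hz, wait_ms) {
  check_scalar(freq_hz, "freq_hz", min = 0, strict_min = TRUE)
  (2 * pi * freq_hz * (wait_ms + latency_ms) / 1000) %% (2 * pi)
}

#' Individualized stimulation parameter set
#'
#' @param p3_latency_ms Individual P300 peak latency (ms).
#' @param stim_freq_hz Individual stimulation frequency (Hz).
#' @param wait_ms Wait duration (ms); computed from latency and frequency
#'   when omitted.
#' @param amplitude_ma Peak-to-peak stimulation amplitude in mA (default 1).
#' @param ramp_s Ramp duration in s (default 10).
#' @param duration_s Stimulation duration in s (default 1200 = 20 min).
#' @param mode `"stim"` or `"sham"`.
#' @return An object of class `stim_params`.
#' @export
stim_params <- function(p3_latency_ms, stim_freq_hz, wait_ms = NULL,
                        amplitude_ma = 1.0, ramp_s = 10, duration_s = 1200,
                        mode = c("stim", "sham")) {
  mode <- match.arg(mode)
  check_scalar(stim_freq_hz, "stim_freq_hz", min = 0, strict_min = TRUE)
  period <- 1000 / stim_freq_hz
  wait_ms <- wait_ms %||% compute_wait(p3_latency_ms, stim_freq_hz)
  if (wait_ms < 0 || wait_ms >= period) {
    abort("`wait_ms` must lie in [0, period).",
          class = "oddlock_parameter_error")
  }
  structure(list(
    p3_latency_ms = p3_latency_ms,
    stim_freq_hz = stim_freq_hz,
    period_ms = period,
    wait_ms = wait_ms,
    amplitude_ma = amplitude_ma,
    ramp_s = ramp_s,
    duration_s = duration_s,
    mode = mode
  ), class = "stim_params")
}

#' @export
print.stim_params <- function(x, ...) {
  cat("<stim_params>\n")
  cat(sprintf("  P3Lat %g ms | f %g Hz (T = %.1f ms) | wait %.1f ms\n",
              x$p3_latency_ms, x$stim_freq_hz, x$period_ms, x$wait_ms))
  cat(sprintf("  %s, %g mA p-p, %g s (ramp %g s)\n",
              x$mode, x$amplitude_ma, x$duration_s, x$ramp_s))
  invisible(x)
}

#' Phase miss between online and offline parameter estimates
#'
#' Evaluates the phase of the delivered stimulation sinusoid at P300 latency
#' under the online parameters (by construction `pi / 2`) and under the
#' offline (noise-corrected, finer-grid) parameters, keeping the online wait
#' that was actually applied. The miss is the circular distance of the two
#' phases, in `[0, pi]`; the signed difference is kept as a secondary field.
#'
#' @param online A `stim_params` (the delivered protocol).
#' @param offline_latency_ms Offline P300 latency estimate (ms).
#' @param offline_freq_hz Offline stimulation-frequency estimate (Hz).
#' @return One-row tibble: `phase_online_rad`, `phase_offline_rad`,
#'   `miss_rad`, `signed_diff_rad`.
#' @export
phase_miss <- function(online, offline_latency_ms, offline_freq_hz) {
  ph_on <- stimulation_phase_at(online$p3_latency_ms, online$stim_freq_hz,
                                online$wait_ms)
  ph_off <- stimulation_phase_at(offline_latency_ms, offline_freq_hz,
                                 online$wait_ms)
  d <- (ph_off - ph_on) %% (2 * pi)
  signed <- if (d > pi) d - 2 * pi else d
  tibble(phase_online_rad = ph_on,
         phase_offline_rad = ph_off,
         miss_rad = abs(signed),
         signed_diff_rad = signed)
}

#' Schedule the during-block stimulus train
#'
#' Replays the presentation loop of the stimulation block: after each
#' stimulus (1000 ms) and its jittered ISI, presentation waits for the next
#' rising zero-crossing trigger of the tACS sine (at multiples of the
#' period), adds the individual wait, then presents the next stimulus.
#' Scheduling stops when `duration_s` elapses, so higher stimulation
#' frequencies fit more trials into the fixed 20 min block. Onsets are
#' quantized to the sample grid; every onset satisfies
#' `stimulation_phase_at(L, f, onset mod T) == pi / 2` to within one sample.
#'
#' @param params A `stim_params`.
#' @param cfg A [sim_config()] (stimulus duration, ISI range, sampling rate,
#'   target probability).
#' @param seed Integer seed.
#' @return A `trial_schedule` tibble with additional columns
#'   `zero_cross_ms` (the trigger used) and `slack_ms` (idle time between
#'   ISI end and that trigger).
#' @export
schedule_during_block <- function(params, cfg = sim_config(),
                                  seed = cfg$seed) {
  period <- params$period_ms
  dur_ms <- params$duration_s * 1000
  dt <- 1000 / cfg$sampling_rate_hz
  onsets <- numeric(0)
  zc <- numeric(0)
  slack <- numeric(0)
  isis <- numeric(0)
  types <- character(0)
  withr::with_seed(seed, {
    t <- 0
    repeat {
      # wait for the next rising zero-crossing at or after t, then add wait
      next_zc <- ceiling(t / period) * period
      onset <- next_zc + params$wait_ms
      onset <- round(onset / dt) * dt          # sample quantization
      if (onset + cfg$stim_duration_ms > dur_ms) break
      isi <- runif(1, cfg$isi_range_ms[1], cfg$isi_range_ms[2])
      onsets <- c(onsets, onset)
      zc <- c(zc, next_zc)
      slack <- c(slack, next_zc - t)
      isis <- c(isis, isi)
      types <- c(types, if (runif(1) < cfg$p_target) "target" else
        "standard")
      t <- onset + cfg$stim_duration_ms + isi
    }
  })
  out <- tibble(
    trial = seq_along(onsets),
    onset_ms = onsets,
    stimulus_type = types,
    isi_ms = isis,
    zero_cross_ms = zc,
    slack_ms = slack
  )
  class(out) <- c("trial_schedule", class(out))
  out
}

#' Generate the tACS waveform
#'
#' `stim` mode: a DC-free sinusoid with linear amplitude ramps over the first
#' and last `ramp_s` seconds and the full peak-to-peak amplitude in between.
#' `sham` mode: the same 10 s fade-in immediately followed by a 10 s
#' fade-out, zero for the rest of the block — the standard active-sham used
#' for blinding.
#'
#' @param params A `stim_params`.
#' @param rate_hz Sampling rate of the generated signal (>= 4x the
#'   stimulation frequency).
#' @return A tibble with `time_s` and `current_ma`.
#' @export
generate_waveform <- function(params, rate_hz = 1000) {
  if (rate_hz < 4 * params$stim_freq_hz) {
    abort("`rate_hz` must be at least 4x the stimulation frequency.",
          class = "oddlock_parameter_error")
  }
  t <- seq(0, params$duration_s, by = 1 / rate_hz)
  if (params$mode == "stim") {
    env <- pmin(1, t / params$ramp_s, (params$duration_s - t) / params$ramp_s)
    env <- pmax(env, 0)
  } else {
    env <- pmax(0, pmin(t / params$ramp_s,
                        (2 * params$ramp_s - t) / params$ramp_s))
  }
  current <- (params$amplitude_ma / 2) * env *
    sin(2 * pi * params$stim_freq_hz * t)
  tibble(time_s = t, current_ma = current)
}
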