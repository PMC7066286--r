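#' Configuration of the synthetic oddball session
#'
#' Bundles every knob of the synthetic visual-oddball EEG generator. Defaults
#' describe the task as run in individualized P300-tACS studies: 400 trials,
#' 25% targets, 1000 ms stimuli with a 1000-2000 ms uniformly jittered
#' inter-stimulus interval, a 32-channel 10-10 cap digitized at 1000 Hz, and a
#' target-locked delta/theta event-related oscillation (ERO) peaking at Pz
#' 440 ms after stimulus onset.
#'
#' The ERO burst on each target trial is
#' `A * exp(-(t - L)^2 / (2 * sigma^2)) * cos(2 * pi * f0 * (t - L))`,
#' so its maximum `A` (`ero_amp_uv`) falls exactly at `ero_latency_ms`
#' post-onset. Background noise is pink (power ~ 1/f). Blink artifacts are a
#' fixed biphasic template, largest frontally, inserted on a random subset of
#' trials.
#'
#' @param n_trials Number of trials in the block.
#' @param p_target Probability that a trial is a target (`X`) rather than a
#'   standard (`O`).
#' @param stim_duration_ms Stimulus presentation time in ms.
#' @param isi_range_ms Length-2 numeric, low and high bound of the uniform
#'   inter-stimulus interval in ms.
#' @param sampling_rate_hz Digitization rate in Hz.
#' @param n_channels Number of EEG channels (a subset of the 32-channel 10-10
#'   montage, always including Pz and the frontal channels).
#' @param ero_freq_hz Frequency of the embedded P300 ERO in Hz.
#' @param ero_latency_ms Peak latency of the ERO after stimulus onset, ms.
#' @param ero_amp_uv Peak amplitude of the ERO at Pz, microvolts.
#' @param ero_width_ms Standard deviation of the Gaussian temporal envelope,
#'   ms.
#' @param noise_rms_uv RMS of the pink background noise per channel,
#'   microvolts.
#' @param blink_prob Per-trial probability of a blink artifact within 0-1 s
#'   post-onset.
#' @param blink_amp_uv Blink peak amplitude at the frontal pole, microvolts.
#' @param rt_mean_ms,rt_sd_ms Mean and SD of the (truncated normal) reaction
#'   time distribution, ms.
#' @param p_omission Probability that a target receives no button press.
#' @param p_commission Probability that a standard receives a button press.
#' @param rt_couple_ero If `TRUE`, reaction times track the ERO latency
#'   (`rt = ero_latency_ms + rt_lag_ms + noise`) instead of being drawn around
#'   `rt_mean_ms`; emulates the P300-latency/RT relationship.
#' @param rt_lag_ms Lag added to `ero_latency_ms` when `rt_couple_ero` is on.
#' @param seed Integer RNG seed stored with the config (used when the calling
#'   function is not given one explicitly).
#'
#' @return An object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(n_trials = 40, seed = 1)
#' cfg$p_target
sim_config <- function(n_trials = 400,
                       p_target = 0.25,
                       stim_duration_ms = 1000,
                       isi_range_ms = c(1000, 2000),
                       sampling_rate_hz = 1000,
                       n_channels = 32,
                       ero_freq_hz = 3,
                       ero_latency_ms = 440,
                       ero_amp_uv = 8,
                       ero_width_ms = 200,
                       noise_rms_uv = 10,
                       blink_prob = 0.1,
                       blink_amp_uv = 150,
                       rt_mean_ms = 450,
                       rt_sd_ms = 100,
                       p_omission = 0.05,
                       p_commission = 0.01,
                       rt_couple_ero = FALSE,
                       rt_lag_ms = 60,
                       seed = 1L) {
  check_scalar(n_trials, "n_trials", min = 1)
  check_prob(p_target, "p_target")
  check_prob(blink_prob, "blink_prob")
  check_prob(p_omission, "p_omission")
  check_prob(p_commission, "p_commission")
  check_scalar(stim_duration_ms, "stim_duration_ms", min = 0, strict_min = TRUE)
  if (length(isi_range_ms) != 2L || isi_range_ms[1] > isi_range_ms[2] ||
      any(isi_range_ms < 0)) {
    abort("`isi_range_ms` must be c(low, high) with 0 <= low <= high.",
          class = "oddlock_parameter_error")
  }
  check_scalar(sampling_rate_hz, "sampling_rate_hz", min = 0, strict_min = TRUE)
  check_scalar(n_channels, "n_channels", min = 1, max = 32)
  check_scalar(ero_freq_hz, "ero_freq_hz", min = 0, strict_min = TRUE)
  check_scalar(ero_latency_ms, "ero_latency_ms",
               min = 0, max = stim_duration_ms)
  check_scalar(ero_amp_uv, "ero_amp_uv", min = 0)
  check_scalar(ero_width_ms, "ero_width_ms", min = 0, strict_min = TRUE)
  check_scalar(noise_rms_uv, "noise_rms_uv", min = 0)
  check_scalar(blink_amp_uv, "blink_amp_uv", min = 0)
  check_scalar(rt_mean_ms, "rt_mean_ms", min = 0, strict_min = TRUE)
  check_scalar(rt_sd_ms, "rt_sd_ms", min = 0)

  structure(list(
    n_trials = as.integer(n_trials),
    p_target = p_target,
    stim_duration_ms = stim_duration_ms,
    isi_range_ms = as.numeric(isi_range_ms),
    sampling_rate_hz = sampling_rate_hz,
    n_channels = as.integer(n_channels),
    channels = default_channels(as.integer(n_channels)),
    ero_freq_hz = ero_freq_hz,
    ero_latency_ms = ero_latency_ms,
    ero_amp_uv = ero_amp_uv,
    ero_width_ms = ero_width_ms,
    noise_rms_uv = noise_rms_uv,
    blink_prob = blink_prob,
    blink_amp_uv = blink_amp_uv,
    rt_mean_ms = rt_mean_ms,
    rt_sd_ms = rt_sd_ms,
    p_omission = p_omission,
    p_commission = p_commission,
    rt_couple_ero = isTRUE(rt_couple_ero),
    rt_lag_ms = rt_lag_ms,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d trials, p(target) = %.2f, stimulus %g ms, ISI %g-%g ms\n",
              x$n_trials, x$p_target, x$stim_duration_ms,
              x$isi_range_ms[1], x$isi_range_ms[2]))
  cat(sprintf("  %d channels @ %g Hz\n", x$n_channels, x$sampling_rate_hz))
  cat(sprintf("  ERO: %g Hz, %g uV at %g ms (envelope SD %g ms)\n",
              x$ero_freq_hz, x$ero_amp_uv, x$ero_latency_ms, x$ero_width_ms))
  cat(sprintf("  noise RMS %g uV, blink p = %g (%g uV)\n",
              x$noise_rms_uv, x$blink_prob, x$blink_amp_uv))
  cat(sprintf("  RT ~ N(%g, %g) ms, p(omit) = %g, p(commit) = %g\n",
              x$rt_mean_ms, x$rt_sd_ms, x$p_omission, x$p_commission))
  invisible(x)
}
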