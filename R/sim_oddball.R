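#' Generate an oddball trial sequence
#'
#' Draws trial types independently (Bernoulli with probability `p_target` of a
#' target) and accumulates onsets as `stimulus duration + uniform ISI`, so a
#' 400-trial block at the default timing lasts 400 x 2500 ms = 16.7 min in
#' expectation.
#'
#' @param n_trials Number of trials.
#' @param p_target Target probability.
#' @param cfg A [sim_config()]; supplies stimulus duration and ISI range (and
#'   defaults for `n_trials`/`p_target` when those are `NULL`).
#' @param seed Integer seed; the schedule is reproducible given the seed.
#'
#' @return A tibble of class `trial_schedule` with columns `trial`,
#'   `onset_ms` (session time of stimulus onset), `stimulus_type`
#'   (`"standard"`/`"target"`) and `isi_ms` (the interval following the
#'   stimulus).
#' @export
#' @examples
#' generate_trial_sequence(10, 0.25, seed = 42)
generate_trial_sequence <- function(n_trials = NULL, p_target = NULL,
                                    cfg = sim_config(), seed = cfg$seed) {
  n_trials <- n_trials %||% cfg$n_trials
  p_target <- p_target %||% cfg$p_target
  check_scalar(n_trials, "n_trials", min = 1)
  check_prob(p_target, "p_target")
  n_trials <- as.integer(n_trials)
  withr::with_seed(seed, {
    types <- ifelse(runif(n_trials) < p_target, "target", "standard")
    isi <- runif(n_trials, cfg$isi_range_ms[1], cfg$isi_range_ms[2])
  })
  onsets <- c(0, cumsum(cfg$stim_duration_ms + isi))[seq_len(n_trials)]
  out <- tibble(
    trial = seq_len(n_trials),
    onset_ms = onsets,
    stimulus_type = types,
    isi_ms = isi
  )
  class(out) <- c("trial_schedule", class(out))
  out
}

# internal: truncated-normal draws on (lo, hi] via inverse-CDF
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Generate the behavioral response stream for a schedule
#'
#' Each target is responded to with probability `1 - p_omission`, with a
#' reaction time drawn from a normal distribution truncated to
#' `(0, stimulus + ISI]` (the response window of that trial). Each standard
#' attracts a false-alarm press with probability `p_commission`. A reaction
#' time is present exactly when a response occurred.
#'
#' @param schedule A `trial_schedule` from [generate_trial_sequence()].
#' @param cfg A [sim_config()] supplying the RT distribution and error rates.
#' @param seed Integer seed.
#'
#' @return A tibble of class `behavior_table` with columns `trial`,
#'   `stimulus_type`, `responded` (logical) and `rt_ms` (`NA` when no
#'   response).
#' @export
#' @examples
#' sched <- generate_trial_sequence(20, 0.25, seed = 1)
#' generate_behavior(sched, sim_config(), seed = 2)
generate_behavior <- function(schedule, cfg = sim_config(), seed = cfg$seed) {
  if (nrow(schedule) == 0) {
    abort("`schedule` must contain at least one trial.",
          class = "oddlock_parameter_error")
  }
  n <- nrow(schedule)
  is_target <- schedule$stimulus_type == "target"
  window_hi <- cfg$stim_duration_ms + schedule$isi_ms
  rt_mu <- if (cfg$rt_couple_ero) cfg$ero_latency_ms + cfg$rt_lag_ms else
    cfg$rt_mean_ms
  withr::with_seed(seed, {
    responded <- logical(n)
    responded[is_target] <- runif(sum(is_target)) >= cfg$p_omission
    responded[!is_target] <- runif(sum(!is_target)) < cfg$p_commission
    rt <- rep(NA_real_, n)
    rt[responded] <- rtruncnorm(sum(responded), rt_mu, cfg$rt_sd_ms,
                                0, window_hi[responded])
  })
  out <- tibble(
    trial = schedule$trial,
    stimulus_type = schedule$stimulus_type,
    responded = responded,
    rt_ms = rt
  )
  class(out) <- c("behavior_table", class(out))
  out
}

# internal: pink (1/f) noise, one channel, via spectral shaping of white
# Gaussian noise; scaled to the requested RMS.
pink_noise <- function(n, rms) {
  if (rms == 0) return(numeric(n))
  nfft <- stats::nextn(n, 2)
  w <- rnorm(nfft)
  spec <- fft(w)
  f <- c(1, seq_len(nfft - 1))          # guard DC bin
  f <- pmin(f, nfft - f + 1)            # two-sided frequency index
  spec <- spec / sqrt(f)
  x <- Re(fft(spec, inverse = TRUE))[seq_len(n)]
  x * rms / sqrt(mean(x^2))
}

# internal: biphasic blink template, ~400 ms, two opposed half-Gaussians,
# peak value 1
blink_template <- function(sfreq) {
  t <- seq(0, 400, by = 1000 / sfreq)
  pos <- exp(-(t - 130)^2 / (2 * 55^2))
  neg <- exp(-(t - 280)^2 / (2 * 70^2))
  w <- pos - 0.6 * neg
  w / max(w)
}

#' Synthesize a continuous oddball EEG recording
#'
#' Builds the multichannel record the rest of the pipeline consumes: pink
#' (1/f) background noise on every channel; on each target trial a windowed
#' delta/theta burst
#' `A * exp(-(t - L)^2 / (2 * sigma^2)) * cos(2 * pi * f0 * (t - L))`
#' whose maximum `A` falls exactly at `onset + L` at Pz, projected to the
#' other channels with a cosine falloff over 10-10 great-circle distance
#' (parietal topography); stereotyped biphasic blink artifacts, largest
#' frontally but sharing one time course on all channels, inserted on
#' `blink_prob` of the trials within 0-1 s post-onset; and stimulus plus
#' response event markers.
#'
#' @param schedule A `trial_schedule`.
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param behavior Optional `behavior_table`; generated (from `seed + 1`) when
#'   omitted, so response markers are always present.
#' @param amp_scale Multiplier applied to the ERO amplitude (used by the study
#'   driver to emulate a tACS effect on post-condition trials).
#'
#' @return An [eeg_recording()]; total length is the last onset plus the
#'   stimulus duration, the maximum ISI and a 4 s tail, so the widest epoch
#'   window fits around every trial.
#' @export
#' @examples
#' cfg <- sim_config(n_trials = 5, n_channels = 4, seed = 7)
#' sched <- generate_trial_sequence(cfg = cfg)
#' synthesize_eeg(sched, cfg)
synthesize_eeg <- function(schedule, cfg = sim_config(), seed = cfg$seed,
                           behavior = NULL, amp_scale = 1) {
  if (cfg$ero_latency_ms < 0 || cfg$ero_latency_ms > cfg$stim_duration_ms) {
    abort("`ero_latency_ms` must lie within the stimulus window.",
          class = "oddlock_parameter_error")
  }
  sfreq <- cfg$sampling_rate_hz
  dt <- 1000 / sfreq
  lead_ms <- 4000    # pre-session recording so the widest epoch fits trial 1
  total_ms <- lead_ms + max(schedule$onset_ms) + cfg$stim_duration_ms +
    cfg$isi_range_ms[2] + 4000
  n_samp <- as.integer(ceiling(total_ms / dt)) + 1L
  channels <- cfg$channels
  n_ch <- length(channels)
  if (is.null(behavior)) {
    behavior <- generate_behavior(schedule, cfg, seed = seed + 1L)
  }

  withr::with_seed(seed, {
    data <- matrix(0, nrow = n_ch, ncol = n_samp, dimnames = list(channels))
    for (ci in seq_len(n_ch)) {
      data[ci, ] <- pink_noise(n_samp, cfg$noise_rms_uv)
    }
    blink_trials <- which(runif(nrow(schedule)) < cfg$blink_prob)
    blink_offset_ms <- runif(length(blink_trials), 0, 600)
  })

  # ERO burst on targets, parietal profile
  w_ero <- spatial_profile(channels, "Pz")
  sigma <- cfg$ero_width_ms
  burst_t <- seq(-5 * sigma, 5 * sigma, by = dt)
  burst <- cfg$ero_amp_uv * amp_scale *
    exp(-burst_t^2 / (2 * sigma^2)) * cos(2 * pi * cfg$ero_freq_hz *
                                            burst_t / 1000)
  targets <- schedule[schedule$stimulus_type == "target", ]
  for (k in seq_len(nrow(targets))) {
    peak <- 1L + ms_to_samples(lead_ms + targets$onset_ms[k] +
                                 cfg$ero_latency_ms, sfreq)
    idx <- peak + ms_to_samples(burst_t, sfreq)
    keep <- idx >= 1L & idx <= n_samp
    data[, idx[keep]] <- data[, idx[keep]] +
      outer(w_ero, burst[keep])
  }

  # blink artifacts: one template time course on every channel (the
  # "uniform" rejection cue is the shared waveform), amplitude decaying
  # towards posterior sites with a 20% floor — the typical parietal residue
  # of an ocular potential in monopolar recordings
  if (length(blink_trials) > 0 && cfg$blink_amp_uv > 0) {
    w_blink <- cfg$blink_amp_uv *
      (0.2 + 0.8 * (spatial_profile(channels, "Fp1") +
                      spatial_profile(channels, "Fp2")) / 2)
    tmpl <- blink_template(sfreq)
    for (k in seq_along(blink_trials)) {
      start <- 1L + ms_to_samples(lead_ms +
                                    schedule$onset_ms[blink_trials[k]] +
                                    blink_offset_ms[k], sfreq)
      idx <- start + seq_along(tmpl) - 1L
      keep <- idx >= 1L & idx <= n_samp
      data[, idx[keep]] <- data[, idx[keep]] + outer(w_blink, tmpl[keep])
    }
  }

  # event markers: stimuli and responses
  stim_ev <- tibble(
    sample = 1L + ms_to_samples(lead_ms + schedule$onset_ms, sfreq),
    code = schedule$stimulus_type
  )
  resp <- behavior[behavior$responded, ]
  resp_ev <- tibble(
    sample = 1L + ms_to_samples(
      lead_ms + schedule$onset_ms[match(resp$trial, schedule$trial)] +
        resp$rt_ms, sfreq),
    code = "response"
  )
  events <- dplyr::bind_rows(stim_ev, resp_ev)
  events <- events[events$sample >= 1L & events$sample <= n_samp, ]

  eeg_recording(data, sfreq, channels, events, reference = "none")
}
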