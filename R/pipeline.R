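#' Preprocess a recording with a named chain
#'
#' Runs the `online` chain (high-pass 0.5 Hz, low-pass 20 Hz, epoch -3 to
#' 4 s, baseline -50 to 0 ms, blink-trial rejection) or the `offline` chain
#' (low-pass 8 Hz, average reference, optional ICA cleanup on top).
#'
#' @param rec An [eeg_recording()].
#' @param preset `"online"` or `"offline"` (see [preprocess_preset()]).
#' @param ... Overrides for individual preset fields (e.g. `low_pass_hz`).
#' @param use_ica Run the ICA blink cleanup in the offline chain. Defaults to
#'   the preset value; the study driver disables it when blink-trial
#'   rejection already removed the contaminated trials.
#' @return An `epoch_set`.
#' @export
preprocess_recording <- function(rec, preset = c("online", "offline"), ...,
                                 use_ica = NULL) {
  p <- modifyList(preprocess_preset(match.arg(preset)), list(...))
  use_ica <- use_ica %||% p$ica
  rec <- filter_signal(rec, high_pass_hz = p$high_pass_hz,
                       low_pass_hz = p$low_pass_hz)
  ep <- epoch_recording(rec, window_ms = p$window_ms,
                        baseline_ms = p$baseline_ms)
  ep <- reject_blink_trials(ep,
                            amp_threshold_uv = p$reject$threshold_uv,
                            uniformity_r = p$reject$uniformity_r,
                            window_ms = p$reject$window_ms)
  if (p$average_reference) ep <- average_reference(ep)
  if (use_ica) ep <- clean_components(ep)
  ep
}

#' Estimate the individualized stimulation parameters
#'
#' The online estimation performed between the pre block and stimulation:
#' P300 latency as the ERP maximum at Pz in the search window, stimulation
#' frequency as the ERSP maximum within +/-150 ms of that latency on the
#' online time-frequency grid, and the wait duration aligning the P300 peak
#' with a stimulation peak.
#'
#' @param ep A preprocessed (online chain) `epoch_set`.
#' @param latency_window_ms P300 search window (default `c(300, 600)`; use
#'   `c(0, 900)` for the initial wide window).
#' @param tfr Time-frequency grid, a [tfr_preset()] list.
#' @param channel Estimation channel (default `"Pz"`).
#' @param decim Decimation factor for the wavelet transform.
#' @param mode `"stim"` or `"sham"` (sham protocols are parameterized the
#'   same way, for blinding).
#' @param duration_s Stimulation duration in seconds.
#' @return A `stim_params` with the ERSP map attached as attribute `ersp`.
#' @export
estimate_stim_params <- function(ep, latency_window_ms = c(300, 600),
                                 tfr = tfr_preset("online"),
                                 channel = "Pz", decim = 4L,
                                 mode = "stim", duration_s = 1200) {
  erp <- compute_erp(ep, channel, "target")
  lat <- estimate_p300_latency(erp, latency_window_ms)
  m <- wavelet_ersp(ep, channel = channel,
                    freq_range_hz = tfr$freq_range_hz,
                    freq_step_hz = tfr$freq_step_hz,
                    n_cycles = tfr$n_cycles,
                    time_step_ms = tfr$time_step_ms,
                    baseline_ms = tfr$baseline_ms,
                    decim = decim)
  f <- estimate_stim_frequency(m, lat$latency_ms)
  out <- stim_params(p3_latency_ms = lat$latency_ms, stim_freq_hz = f,
                     mode = mode, duration_s = duration_s)
  attr(out, "ersp") <- m
  out
}

#' Configuration of a synthetic two-group study
#'
#' Describes the full two-by-two (group x time) design: cohort sizes, the
#' simulation template, the per-subject spread of ERO frequency and latency
#' (drawn from truncated normals matching the observed stimulation-frequency
#' spread, mean 3.0 Hz, SD 1.24 Hz, and a 440 ms pilot latency), and the
#' simulated tACS effect — an ERO amplitude multiplier applied to the
#' post-condition target trials of the stim group.
#'
#' @param n_per_group Subjects per group (default 9).
#' @param sim A [sim_config()] template.
#' @param effect_multiplier Post-condition ERO amplitude multiplier for the
#'   stim group (default 1.3).
#' @param sham_multiplier Same for the sham group (default 1.0).
#' @param freq_mean_hz,freq_sd_hz,freq_range_hz Per-subject ERO frequency
#'   distribution (truncated normal).
#' @param lat_mean_ms,lat_sd_ms,lat_range_ms Per-subject ERO latency
#'   distribution (truncated normal).
#' @param latency_window_ms Online P300 search window.
#' @param during_block Schedule and simulate the during block (behavior
#'   only).
#' @param use_ica Run ICA cleanup in the offline chain.
#' @param seed Base seed; per-subject seeds are derived from it.
#' @param out_dir Output directory for the report bundle, or `NULL` to skip
#'   writing.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_per_group = 9,
                         sim = sim_config(),
                         effect_multiplier = 1.3,
                         sham_multiplier = 1.0,
                         freq_mean_hz = 3.0, freq_sd_hz = 1.24,
                         freq_range_hz = c(2, 7),
                         lat_mean_ms = 440, lat_sd_ms = 50,
                         lat_range_ms = c(350, 550),
                         latency_window_ms = c(300, 600),
                         during_block = TRUE,
                         use_ica = FALSE,
                         seed = 1L,
                         out_dir = NULL) {
  check_scalar(n_per_group, "n_per_group", min = 1)
  check_scalar(effect_multiplier, "effect_multiplier", min = 0,
               strict_min = TRUE)
  check_scalar(sham_multiplier, "sham_multiplier", min = 0,
               strict_min = TRUE)
  structure(list(
    n_per_group = as.integer(n_per_group),
    sim = sim,
    effect_multiplier = effect_multiplier,
    sham_multiplier = sham_multiplier,
    freq_mean_hz = freq_mean_hz, freq_sd_hz = freq_sd_hz,
    freq_range_hz = freq_range_hz,
    lat_mean_ms = lat_mean_ms, lat_sd_ms = lat_sd_ms,
    lat_range_ms = lat_range_ms,
    latency_window_ms = latency_window_ms,
    during_block = isTRUE(during_block),
    use_ica = isTRUE(use_ica),
    seed = as.integer(seed),
    out_dir = out_dir
  ), class = "study_config")
}

# internal: simulate and analyze one subject; returns outcome rows, the
# delivered protocol and the phase miss.
run_subject <- function(subject, group, cfg) {
  seed <- cfg$seed + 1000L * subject
  withr::with_seed(seed, {
    f0 <- rtruncnorm(1, cfg$freq_mean_hz, cfg$freq_sd_hz,
                     cfg$freq_range_hz[1], cfg$freq_range_hz[2])
    l0 <- rtruncnorm(1, cfg$lat_mean_ms, cfg$lat_sd_ms,
                     cfg$lat_range_ms[1], cfg$lat_range_ms[2])
  })
  sim <- cfg$sim
  sim$ero_freq_hz <- f0
  sim$ero_latency_ms <- l0
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage `%s` failed for subject %d: %s",
                    name, subject, conditionMessage(e)),
            class = "oddlock_stage_error")
    })
  }

  # pre block
  sched_pre <- stage("simulate-pre",
                     generate_trial_sequence(cfg = sim, seed = seed))
  behav_pre <- stage("simulate-pre",
                     generate_behavior(sched_pre, sim, seed = seed + 1L))
  rec_pre <- stage("simulate-pre",
                   synthesize_eeg(sched_pre, sim, seed = seed + 2L,
                                  behavior = behav_pre))

  # online estimation on the pre block
  ep_online <- stage("preprocess-online",
                     preprocess_recording(rec_pre, "online"))
  params <- stage("estimate-params",
                  estimate_stim_params(
                    ep_online, latency_window_ms = cfg$latency_window_ms,
                    mode = if (group == "stim") "stim" else "sham"))

  # during block: phase-locked schedule, behavior only (EEG carries the
  # stimulation artifact and is not analyzed)
  during <- NULL
  if (cfg$during_block) {
    sched_dur <- stage("schedule-during",
                       schedule_during_block(params, sim, seed = seed + 3L))
    behav_dur <- stage("simulate-during",
                       generate_behavior(sched_dur, sim, seed = seed + 4L))
    during <- list(schedule = sched_dur, behavior = behav_dur)
  }

  # post block with the simulated tACS effect on the ERO amplitude
  mult <- if (group == "stim") cfg$effect_multiplier else cfg$sham_multiplier
  sched_post <- stage("simulate-post",
                      generate_trial_sequence(cfg = sim, seed = seed + 5L))
  behav_post <- stage("simulate-post",
                      generate_behavior(sched_post, sim, seed = seed + 6L))
  rec_post <- stage("simulate-post",
                    synthesize_eeg(sched_post, sim, seed = seed + 7L,
                                   behavior = behav_post, amp_scale = mult))

  # offline chain and outcomes, pre and post
  tfr_off <- tfr_preset("offline")
  one_condition <- function(rec, sched, behav, condition) {
    ep <- stage("preprocess-offline",
                preprocess_recording(rec, "offline",
                                     use_ica = cfg$use_ica))
    p3 <- stage("outcomes", p300_metrics(ep))
    m <- stage("outcomes",
               wavelet_ersp(ep, freq_range_hz = tfr_off$freq_range_hz,
                            freq_step_hz = tfr_off$freq_step_hz,
                            n_cycles = tfr_off$n_cycles,
                            time_step_ms = tfr_off$time_step_ms,
                            baseline_ms = tfr_off$baseline_ms,
                            decim = 8L))
    # ERSP maximum in the +/-3 Hz, +/-150 ms window around the delivered
    # stimulation parameters
    emax <- stage("outcomes",
                  ersp_window_max(m, center_time_ms = params$p3_latency_ms,
                                  time_halfwidth_ms = 150,
                                  center_freq_hz = params$stim_freq_hz,
                                  freq_halfwidth_hz = 3))
    rt <- reaction_time_metrics(behav)
    err <- error_counts(sched, behav)
    list(
      row = tibble(
        subject = subject, group = group, condition = condition,
        p3_amp_uv = p3$p3_amp_uv, p3_lat_ms = p3$p3_lat_ms,
        rt_mean_ms = rt$rt_mean_ms, rt_sd_ms = rt$rt_sd_ms,
        n_valid_rt = rt$n_valid_rt,
        omissions = err$omissions, commissions = err$commissions,
        ersp_max_db = emax$value_db,
        n_trials_used = p3$n_trials_used),
      epochs = ep, ersp = m)
  }
  pre <- one_condition(rec_pre, sched_pre, behav_pre, "pre")
  post <- one_condition(rec_post, sched_post, behav_post, "post")

  rows <- dplyr::bind_rows(pre$row, post$row)
  if (!is.null(during)) {
    rt <- reaction_time_metrics(during$behavior)
    err <- error_counts(during$schedule, during$behavior)
    rows <- dplyr::bind_rows(rows, tibble(
      subject = subject, group = group, condition = "during",
      p3_amp_uv = NA_real_, p3_lat_ms = NA_real_,
      rt_mean_ms = rt$rt_mean_ms, rt_sd_ms = rt$rt_sd_ms,
      n_valid_rt = rt$n_valid_rt,
      omissions = err$omissions, commissions = err$commissions,
      ersp_max_db = NA_real_,
      n_trials_used = NA_integer_))
  }

  # offline (noise-corrected, finer-grid) parameter estimates -> phase miss
  erp_off <- compute_erp(pre$epochs)
  lat_off <- estimate_p300_latency(erp_off, cfg$latency_window_ms)
  f_off <- estimate_stim_frequency(pre$ersp, lat_off$latency_ms)
  pm <- phase_miss(params, lat_off$latency_ms, f_off)

  list(rows = rows, params = params,
       phase_miss = dplyr::mutate(pm, subject = subject, group = group,
                                  online_lat_ms = params$p3_latency_ms,
                                  online_freq_hz = params$stim_freq_hz,
                                  offline_lat_ms = lat_off$latency_ms,
                                  offline_freq_hz = f_off,
                                  .before = 1),
       true_freq_hz = f0, true_lat_ms = l0,
       during = during)
}

#' Run a full synthetic two-group study
#'
#' Simulates every subject's pre block, runs the online estimation, schedules
#' the phase-locked during block, simulates the post block with the
#' configured tACS effect, extracts outcomes through the offline chain, and
#' runs the group statistics. Fully deterministic given the config seed.
#'
#' @param cfg A [study_config()].
#' @return An object of class `oddlock_study`: `$outcomes` (long outcome
#'   table), `$changes`, `$stats` (hypothesis suite), `$correlations`,
#'   `$phase_miss`, `$subjects` (true and estimated per-subject parameters),
#'   `$config`. When `cfg$out_dir` is set the bundle (CSV/JSON/TSV plus a
#'   plain-text report) is also written there.
#' @export
run_study <- function(cfg = study_config()) {
  subjects <- tibble(
    subject = seq_len(2 * cfg$n_per_group),
    group = rep(c("stim", "sham"), each = cfg$n_per_group)
  )
  res <- purrr::pmap(subjects, function(subject, group) {
    run_subject(subject, group, cfg)
  })
  outcomes <- build_outcome_table(
    dplyr::bind_rows(purrr::map(res, "rows")))
  changes <- change_table(outcomes,
                          measures = c(p3_amp_uv = "relative",
                                       rt_mean_ms = "relative",
                                       rt_sd_ms = "relative",
                                       omissions = "absolute",
                                       commissions = "absolute"))
  stats <- run_hypothesis_suite(outcomes)
  correlations <- tryCatch(
    correlate_changes(dplyr::bind_rows(
      changes,
      dplyr::bind_rows(purrr::map(res, "phase_miss")) |>
        dplyr::transmute(subject = .data$subject, group = .data$group,
                         measure = "phase_miss_rad",
                         comparison = "pre-to-post", basis = "absolute",
                         value = .data$miss_rad))),
    error = function(e) NULL)
  subj_tbl <- subjects |>
    dplyr::mutate(
      true_freq_hz = purrr::map_dbl(res, "true_freq_hz"),
      true_lat_ms = purrr::map_dbl(res, "true_lat_ms"),
      est_freq_hz = purrr::map_dbl(res, ~ .x$params$stim_freq_hz),
      est_lat_ms = purrr::map_dbl(res, ~ .x$params$p3_latency_ms),
      wait_ms = purrr::map_dbl(res, ~ .x$params$wait_ms),
      n_during_trials = purrr::map_int(res, ~ {
        if (is.null(.x$during)) NA_integer_ else nrow(.x$during$schedule)
      })
    )
  out <- structure(list(
    outcomes = outcomes,
    changes = changes,
    stats = stats,
    correlations = correlations,
    phase_miss = dplyr::bind_rows(purrr::map(res, "phase_miss")),
    subjects = subj_tbl,
    params = purrr::map(res, "params"),
    config = cfg
  ), class = "oddlock_study")
  if (!is.null(cfg$out_dir)) write_study_bundle(out, cfg$out_dir)
  out
}

#' @export
print.oddlock_study <- function(x, ...) {
  cat("<oddlock_study>\n")
  cat(sprintf("  %d subjects per group, effect multiplier %g (sham %g)\n",
              x$config$n_per_group, x$config$effect_multiplier,
              x$config$sham_multiplier))
  amp <- x$stats[x$stats$measure == "p3_amp_uv", ]
  if (nrow(amp) == 1) {
    cat(sprintf(
      "  amplitude change stim %.2f%% vs sham %.2f%%: W = %g, p = %.3f\n",
      amp$mean_stim, amp$mean_sham, amp$rank_sum_w, amp$p_raw))
  }
  invisible(x)
}

# internal: write the report bundle of a finished study
write_study_bundle <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_outcomes_csv(study$outcomes, file.path(out_dir, "outcomes.csv"))
  write_outcomes_csv(study$changes, file.path(out_dir, "changes.csv"))
  readr::write_csv(study$stats, file.path(out_dir, "group_stats.csv"))
  readr::write_csv(study$phase_miss, file.path(out_dir, "phase_miss.csv"))
  readr::write_csv(study$subjects, file.path(out_dir, "subjects.csv"))
  pdir <- file.path(out_dir, "stim_params")
  dir.create(pdir, showWarnings = FALSE)
  purrr::iwalk(study$params, function(p, i) {
    write_stim_params(p, file.path(pdir, sprintf("subject_%02d.json", i)))
  })
  cfg <- study$config
  report <- c(
    "Synthetic phase-locked tACS oddball study",
    sprintf("subjects per group: %d", cfg$n_per_group),
    sprintf("effect multiplier (stim/sham): %g / %g",
            cfg$effect_multiplier, cfg$sham_multiplier),
    sprintf("P300 search window: %g-%g ms", cfg$latency_window_ms[1],
            cfg$latency_window_ms[2]),
    "online TFR grid: 1.5-20 Hz, 0.5 Hz, 24 ms, 3 cycles",
    "offline TFR grid: 0.8-10 Hz, 0.25 Hz, 14 ms, 3 cycles",
    sprintf("online filters: HP %g Hz, LP %g Hz; offline LP %g Hz",
            preprocess_preset("online")$high_pass_hz,
            preprocess_preset("online")$low_pass_hz,
            preprocess_preset("offline")$low_pass_hz),
    sprintf("blink rejection: %g uV threshold, uniformity r %g, 0-1 s",
            preprocess_preset("online")$reject$threshold_uv,
            preprocess_preset("online")$reject$uniformity_r),
    sprintf("ICA cleanup: %s", if (cfg$use_ica) "on" else "off"),
    sprintf("simulation: %d trials, p(target) %g, ERO %g uV (SD %g ms), noise %g uV",
            cfg$sim$n_trials, cfg$sim$p_target, cfg$sim$ero_amp_uv,
            cfg$sim$ero_width_ms, cfg$sim$noise_rms_uv),
    sprintf("base seed: %d", cfg$seed),
    "",
    "Hypothesis tests:",
    utils::capture.output(as.data.frame(study$stats))
  )
  writeLines(report, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}
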