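#' P300 amplitude and latency from epochs
#'
#' Averages the retained target epochs at the requested channel (omission
#' trials stay in the EEG average; they only leave the reaction-time
#' analysis) and returns the window maximum of the averaged waveform in
#' microvolts together with its time. Ties go to the earliest time.
#'
#' @param ep An `epoch_set`.
#' @param channel Channel label (default `"Pz"`).
#' @param window_ms Closed search window (default 300-600 ms).
#' @return One-row tibble: `p3_amp_uv`, `p3_lat_ms`, `n_trials_used`,
#'   `at_boundary`.
#' @export
p300_metrics <- function(ep, channel = "Pz", window_ms = c(300, 600)) {
  erp <- compute_erp(ep, channel, "target")
  est <- estimate_p300_latency(erp, window_ms)
  tibble(p3_amp_uv = est$amp_uv,
         p3_lat_ms = est$latency_ms,
         n_trials_used = attr(erp, "n_trials"),
         at_boundary = est$at_boundary)
}

#' Reaction-time mean and variability
#'
#' Mean (RT-M) and sample standard deviation (RT-V, `n - 1` denominator)
#' over responded target trials with reaction times inside the closed
#' validity interval (default 200-1000 ms; trials outside are invalid and
#' excluded from all reaction-time analyses).
#'
#' @param behavior A `behavior_table`.
#' @param valid_range_ms Closed validity interval in ms.
#' @return One-row tibble: `rt_mean_ms`, `rt_sd_ms` (`NA` with fewer than two
#'   valid trials), `n_valid_rt`, `n_invalid_rt`.
#' @export
#' @examples
#' b <- tibble::tibble(trial = 1:4, stimulus_type = "target",
#'                     responded = TRUE, rt_ms = c(150, 500, 600, 1100))
#' reaction_time_metrics(b)
reaction_time_metrics <- function(behavior, valid_range_ms = c(200, 1000)) {
  rt <- behavior$rt_ms[behavior$stimulus_type == "target" &
                         behavior$responded]
  valid <- rt[rt >= valid_range_ms[1] & rt <= valid_range_ms[2]]
  n <- length(valid)
  if (n < 2) {
    warn(sprintf("Only %d valid reaction time(s); SD unavailable.", n))
  }
  tibble(
    rt_mean_ms = if (n >= 1) mean(valid) else NA_real_,
    rt_sd_ms = if (n >= 2) sd(valid) else NA_real_,
    n_valid_rt = n,
    n_invalid_rt = length(rt) - n
  )
}

#' Omission and commission error counts
#'
#' Omissions: targets without any button press. Commissions (false alarms):
#' standards with a button press.
#'
#' @param schedule A `trial_schedule`.
#' @param behavior A `behavior_table` aligned to it (same trials).
#' @return One-row tibble: `omissions`, `commissions`, `n_targets`,
#'   `n_standards`.
#' @export
error_counts <- function(schedule, behavior) {
  if (!identical(schedule$trial, behavior$trial)) {
    abort("`behavior` is not aligned to `schedule` (trial indices differ).",
          class = "oddlock_parameter_error")
  }
  is_target <- schedule$stimulus_type == "target"
  tibble(
    omissions = sum(is_target & !behavior$responded),
    commissions = sum(!is_target & behavior$responded),
    n_targets = sum(is_target),
    n_standards = sum(!is_target)
  )
}

#' Relative change in percent
#'
#' `(later - pre) / pre * 100`. A zero baseline is an error: error counts,
#' which can legitimately be zero, are compared as absolute differences
#' instead.
#'
#' @param pre_value Baseline value (nonzero).
#' @param later_value Later value.
#' @return Percent change.
#' @export
#' @examples
#' relative_change(8, 10)   # +25%
relative_change <- function(pre_value, later_value) {
  if (any(pre_value == 0)) {
    abort(paste("Zero baseline: relative change undefined;",
                "use an absolute difference for count measures."),
          class = "oddlock_zero_baseline_error")
  }
  (later_value - pre_value) / pre_value * 100
}

#' Assemble the long-format outcome table
#'
#' One row per subject x condition, collecting the per-condition outcome
#' measures. Subjects missing a required condition (pre and post; during is
#' optional and behavior-only) are dropped with a message.
#'
#' @param per_condition A tibble with columns `subject`, `group`
#'   (`"stim"`/`"sham"`), `condition` (`"pre"`/`"during"`/`"post"`) and the
#'   outcome columns (`p3_amp_uv`, `p3_lat_ms`, `rt_mean_ms`, `rt_sd_ms`,
#'   `n_valid_rt`, `omissions`, `commissions`, `ersp_max_db`, ... missing
#'   measures as `NA`).
#' @return The validated tibble of class `outcome_set`, ordered by subject
#'   and condition.
#' @export
build_outcome_table <- function(per_condition) {
  req <- c("subject", "group", "condition")
  if (!all(req %in% names(per_condition))) {
    abort("Need columns `subject`, `group`, `condition`.",
          class = "oddlock_parameter_error")
  }
  bad <- per_condition |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(ok = all(c("pre", "post") %in% .data$condition),
                     .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    inform(sprintf("Excluding subject(s) without both pre and post: %s",
                   paste(bad$subject, collapse = ", ")))
    per_condition <- per_condition |>
      dplyr::filter(!.data$subject %in% bad$subject)
  }
  out <- per_condition |>
    dplyr::mutate(condition = factor(.data$condition,
                                     levels = c("pre", "during", "post"))) |>
    dplyr::arrange(.data$subject, .data$condition)
  class(out) <- c("outcome_set", class(out))
  out
}

#' Per-subject change scores between conditions
#'
#' Computes, per subject and measure, the comparison table used by the group
#' statistics: relative percent change for amplitude, reaction-time and ERSP
#' measures, absolute differences for error counts (whose baselines may be
#' zero).
#'
#' @param outcomes An `outcome_set`.
#' @param measures Named character vector mapping measure name to basis
#'   (`"relative"` or `"absolute"`).
#' @param comparisons Character vector among `"pre-to-post"`,
#'   `"pre-to-during"`, `"during-to-post"`.
#' @return A tibble: `subject`, `group`, `measure`, `comparison`, `basis`,
#'   `value`.
#' @export
change_table <- function(outcomes,
                         measures = c(p3_amp_uv = "relative",
                                      rt_mean_ms = "relative",
                                      rt_sd_ms = "relative",
                                      omissions = "absolute",
                                      commissions = "absolute"),
                         comparisons = c("pre-to-post", "pre-to-during",
                                         "during-to-post")) {
  ends <- list("pre-to-post" = c("pre", "post"),
               "pre-to-during" = c("pre", "during"),
               "during-to-post" = c("during", "post"))
  rows <- list()
  wide <- outcomes |>
    tidyr::pivot_longer(cols = names(measures), names_to = "measure",
                        values_to = "value") |>
    tidyr::pivot_wider(id_cols = c("subject", "group", "measure"),
                       names_from = "condition", values_from = "value")
  for (cmp in comparisons) {
    from <- ends[[cmp]][1]
    to <- ends[[cmp]][2]
    if (!all(c(from, to) %in% names(wide))) next
    sub <- wide |>
      dplyr::mutate(
        comparison = cmp,
        basis = unname(measures[.data$measure]),
        value = dplyr::if_else(
          unname(measures[.data$measure]) == "relative",
          (.data[[to]] - .data[[from]]) / .data[[from]] * 100,
          .data[[to]] - .data[[from]])
      ) |>
      dplyr::select("subject", "group", "measure", "comparison", "basis",
                    "value")
    rows[[cmp]] <- sub
  }
  dplyr::bind_rows(rows) |>
    dplyr::filter(!is.na(.data$value))
}
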