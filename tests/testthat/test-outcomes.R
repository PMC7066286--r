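test_that("P300 metrics recover amplitude and latency of the average", {
  cfg <- clean_cfg(n_trials = 12, ero_amp_uv = 10, ero_latency_ms = 440)
  sched <- generate_trial_sequence(cfg = cfg)
  # baseline-free epochs: the burst envelope reaches into -50..0 ms, so
  # baseline correction would shift the noiseless amplitude slightly
  ep <- epoch_recording(synthesize_eeg(sched, cfg), baseline_ms = NULL)
  m <- p300_metrics(ep)
  expect_equal(m$p3_lat_ms, 440)
  expect_equal(m$p3_amp_uv, 10, tolerance = 1e-6)
  expect_equal(m$n_trials_used, sum(sched$stimulus_type == "target"))

  # linearity: halving every epoch halves the amplitude, not the latency
  ep2 <- ep
  ep2$data <- ep2$data / 2
  m2 <- p300_metrics(ep2)
  expect_equal(m2$p3_amp_uv, m$p3_amp_uv / 2)
  expect_equal(m2$p3_lat_ms, m$p3_lat_ms)
})

test_that("P300 amplitude over a noisy cohort tracks generator truth", {
  cfg <- tiny_cfg(n_trials = 160, ero_amp_uv = 8, ero_latency_ms = 440,
                  blink_prob = 0, seed = 99)
  sched <- generate_trial_sequence(cfg = cfg)
  ep <- epoch_recording(synthesize_eeg(sched, cfg))
  m <- p300_metrics(ep)
  n_tar <- sum(sched$stimulus_type == "target")
  se <- cfg$noise_rms_uv / sqrt(n_tar)
  # window-max of a noisy average is upward-biased; allow the search bias
  expect_lt(abs(m$p3_amp_uv - 8), 4 * se + 1)
  expect_lt(abs(m$p3_lat_ms - 440), 50)
})

test_that("reaction-time metrics apply the closed validity interval", {
  b <- tibble::tibble(trial = 1:4, stimulus_type = "target",
                      responded = TRUE, rt_ms = c(150, 500, 600, 1100))
  m <- reaction_time_metrics(b)
  expect_equal(m$n_valid_rt, 2)
  expect_equal(m$rt_mean_ms, 550)
  expect_equal(m$rt_sd_ms, sd(c(500, 600)))
  expect_equal(m$n_invalid_rt, 2)

  # exact endpoints are valid ("longer than / less than" excludes)
  b2 <- tibble::tibble(trial = 1:2, stimulus_type = "target",
                       responded = TRUE, rt_ms = c(200, 1000))
  expect_equal(reaction_time_metrics(b2)$n_valid_rt, 2)

  # identical RTs: zero variability
  b3 <- tibble::tibble(trial = 1:3, stimulus_type = "target",
                       responded = TRUE, rt_ms = rep(400, 3))
  expect_equal(reaction_time_metrics(b3)$rt_sd_ms, 0)

  # single valid RT: SD absent with a warning
  b4 <- tibble::tibble(trial = 1L, stimulus_type = "target",
                       responded = TRUE, rt_ms = 400)
  expect_warning(m4 <- reaction_time_metrics(b4), "SD unavailable")
  expect_true(is.na(m4$rt_sd_ms))
})

test_that("recovered RT moments match the truncated-normal oracle", {
  cfg <- sim_config(n_trials = 10000, p_target = 1, rt_mean_ms = 450,
                    rt_sd_ms = 100, p_omission = 0, seed = 15)
  sched <- generate_trial_sequence(cfg = cfg, seed = 15)
  b <- generate_behavior(sched, cfg, seed = 16)
  m <- reaction_time_metrics(b)
  # analytic moments of N(450, 100) truncated to the validity window
  o <- truncnorm_moments(450, 100, 200, 1000)
  expect_lt(abs(m$rt_mean_ms - o$mean), 3)
  expect_lt(abs(m$rt_sd_ms - o$sd), 3)
})

test_that("error counts follow their definitions", {
  sched <- tibble::tibble(trial = 1:20,
                          stimulus_type = rep(c("target", "standard"), 10))
  beh <- tibble::tibble(trial = 1:20,
                        stimulus_type = sched$stimulus_type,
                        responded = c(rep(c(TRUE, FALSE), 8),
                                      c(FALSE, TRUE), c(FALSE, TRUE)),
                        rt_ms = NA_real_)
  ec <- error_counts(sched, beh)
  expect_equal(ec$omissions, sum(sched$stimulus_type == "target" &
                                   !beh$responded))
  expect_equal(ec$commissions, sum(sched$stimulus_type == "standard" &
                                     beh$responded))

  # no responses anywhere
  beh2 <- beh
  beh2$responded <- FALSE
  ec2 <- error_counts(sched, beh2)
  expect_equal(ec2$omissions, ec2$n_targets)
  expect_equal(ec2$commissions, 0)

  # generator-level binomial check
  cfg <- sim_config(n_trials = 10000, p_target = 0.5, p_omission = 0.05,
                    seed = 3)
  s <- generate_trial_sequence(cfg = cfg, seed = 3)
  b <- generate_behavior(s, cfg, seed = 4)
  ec3 <- error_counts(s, b)
  expect_lt(abs(ec3$omissions - 0.05 * ec3$n_targets),
            3 * sqrt(ec3$n_targets * 0.05 * 0.95))

  expect_error(error_counts(sched[1:10, ], beh),
               class = "oddlock_parameter_error")
})

test_that("relative change is a guarded percent change", {
  expect_equal(relative_change(8, 10), 25)
  expect_equal(relative_change(7, 7), 0)
  expect_error(relative_change(0, 5), class = "oddlock_zero_baseline_error")
  # scale invariance
  expect_equal(relative_change(3, 4.2), relative_change(3 * 17, 4.2 * 17))
})

test_that("outcome tables assemble, validate and round-trip", {
  base <- tidyr::expand_grid(subject = 1:18,
                             condition = c("pre", "during", "post"))
  base$group <- ifelse(base$subject <= 9, "stim", "sham")
  base$p3_amp_uv <- ifelse(base$condition == "during", NA, 8)
  base$rt_mean_ms <- 450
  oc <- build_outcome_table(base)
  expect_equal(nrow(oc), 54)
  expect_s3_class(oc, "outcome_set")

  # a subject lacking post is excluded with a message
  broken <- base[!(base$subject == 4 & base$condition == "post"), ]
  expect_message(oc2 <- build_outcome_table(broken), "without both")
  expect_false(4 %in% oc2$subject)
  expect_equal(nrow(oc2), 51)

  path <- tempfile(fileext = ".csv")
  write_outcomes_csv(oc, path)
  rt <- read_outcomes_csv(path)
  expect_equal(nrow(rt), 54)
  expect_equal(rt$p3_amp_uv, oc$p3_amp_uv)
})

test_that("change tables use relative or absolute basis per measure", {
  oc <- build_outcome_table(tibble::tibble(
    subject = rep(1:2, each = 3),
    group = rep(c("stim", "sham"), each = 3),
    condition = rep(c("pre", "during", "post"), 2),
    p3_amp_uv = c(8, NA, 10, 10, NA, 9),
    omissions = c(0, 3, 1, 2, 2, 2)
  ))
  ch <- change_table(oc, measures = c(p3_amp_uv = "relative",
                                      omissions = "absolute"))
  amp1 <- ch$value[ch$subject == 1 & ch$measure == "p3_amp_uv" &
                     ch$comparison == "pre-to-post"]
  expect_equal(amp1, 25)    # (10 - 8) / 8 * 100
  om1 <- ch$value[ch$subject == 1 & ch$measure == "omissions" &
                    ch$comparison == "pre-to-post"]
  expect_equal(om1, 1)      # absolute difference handles zero baselines
  expect_true(all(ch$basis[ch$measure == "omissions"] == "absolute"))
})
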