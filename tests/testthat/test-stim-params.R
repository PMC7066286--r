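test_that("P300 latency is the argmax of the ERP in the closed window", {
  t <- 0:900
  erp <- tibble::tibble(time_ms = t, amp_uv = 10 * exp(-(t - 440)^2 / 2e4))
  est <- estimate_p300_latency(erp, c(300, 600))
  expect_equal(est$latency_ms, 440)
  expect_equal(est$amp_uv, 10)
  expect_false(est$at_boundary)

  # monotone-decreasing wave: boundary maximum flagged
  erp2 <- tibble::tibble(time_ms = t, amp_uv = -t)
  est2 <- estimate_p300_latency(erp2, c(300, 600))
  expect_equal(est2$latency_ms, 300)
  expect_true(est2$at_boundary)

  # two equal maxima: earliest wins
  amp <- rep(0, length(t))
  amp[t == 400] <- 5
  amp[t == 500] <- 5
  est3 <- estimate_p300_latency(tibble::tibble(time_ms = t, amp_uv = amp),
                                c(300, 600))
  expect_equal(est3$latency_ms, 400)

  expect_error(estimate_p300_latency(erp, c(-100, 600)),
               class = "oddlock_parameter_error")
})

test_that("stimulation frequency comes from the windowed ERSP maximum", {
  m <- structure(list(
    values = matrix(-10, nrow = 38, ncol = 40),
    freqs_hz = seq(1.5, 20, 0.5),
    times_ms = seq(0, 936, 24),
    baseline_ms = c(-3000, 0), n_cycles = 3, channel = "Pz",
    n_trials = 10), class = "ersp_map")
  # peak at 3 Hz / 432 ms
  m$values[m$freqs_hz == 3, which.min(abs(m$times_ms - 432))] <- 6
  expect_equal(estimate_stim_frequency(m, 440), 3)

  # peak at 600 ms excluded for latency 440 (window 290-590)
  m2 <- m
  m2$values[,] <- -10
  m2$values[m2$freqs_hz == 8, which.min(abs(m2$times_ms - 600))] <- 9
  m2$values[m2$freqs_hz == 2.5, which.min(abs(m2$times_ms - 500))] <- 3
  expect_equal(estimate_stim_frequency(m2, 440), 2.5)
})

test_that("wait duration puts the P300 peak on a stimulation peak", {
  expect_equal(compute_wait(0, 1), 250)
  # oracle: the sine attains its maximum at wait + L
  for (case in list(c(440, 2.5, 60), c(500, 4, 62.5))) {
    w <- compute_wait(case[1], case[2])
    expect_equal(w, case[3])
    expect_equal(sin(2 * pi * case[2] * (w + case[1]) / 1000), 1,
                 tolerance = 1e-12)
  }
  # property: exact quarter-cycle phase for 1000 random (L, f) pairs
  withr::with_seed(5, {
    L <- runif(1000, 0, 900)
    f <- runif(1000, 0.5, 10)
  })
  w <- mapply(compute_wait, L, f)
  expect_true(all(w >= 0 & w < 1000 / f))
  ph <- mapply(stimulation_phase_at, L, f, w)
  expect_equal(ph, rep(pi / 2, 1000), tolerance = 1e-8)
  expect_error(compute_wait(440, 0), class = "oddlock_parameter_error")
})

test_that("stimulation phase evaluation matches direct computation", {
  expect_equal(stimulation_phase_at(440, 3, 60), pi)   # 2*pi*3*0.5 mod 2pi
  # half-period extra wait lands on the trough
  w <- compute_wait(440, 2.5)
  expect_equal(stimulation_phase_at(440, 2.5, w + 200), 3 * pi / 2)
})

test_that("phase miss is a circular distance in [0, pi]", {
  on <- stim_params(440, 2.5)
  expect_equal(phase_miss(on, 440, 2.5)$miss_rad, 0)
  # online (440, 2.5, wait 60) vs offline (440, 3.0): miss pi/2
  pm <- phase_miss(on, 440, 3.0)
  expect_equal(pm$phase_online_rad, pi / 2)
  expect_equal(pm$miss_rad, pi / 2, tolerance = 1e-9)
  # range property over random parameter pairs
  withr::with_seed(8, {
    for (k in 1:50) {
      onk <- stim_params(runif(1, 300, 600), runif(1, 1.5, 8))
      mk <- phase_miss(onk, runif(1, 300, 600), runif(1, 1.5, 8))
      expect_gte(mk$miss_rad, 0)
      expect_lte(mk$miss_rad, pi)
    }
  })
  # symmetry: swapping the two parameter sets preserves the miss
  a <- stim_params(420, 3.5)
  b <- stim_params(470, 2.5, wait_ms = a$wait_ms)
  m_ab <- phase_miss(a, 470, 2.5)$miss_rad
  m_ba <- abs(stimulation_phase_at(470, 2.5, a$wait_ms) -
                stimulation_phase_at(420, 3.5, a$wait_ms))
  m_ba <- min(m_ba, 2 * pi - m_ba)
  expect_equal(m_ab, m_ba, tolerance = 1e-9)
})

test_that("during-block scheduling is phase-locked and frequency-dependent", {
  cfg <- tiny_cfg()
  p <- stim_params(440, 3, duration_s = 600)
  s <- schedule_during_block(p, cfg, seed = 5)
  # every onset is wait (mod period) after a zero-crossing: phase at P3Lat
  # is pi/2 within one sample
  ph <- vapply(s$onset_ms, function(o) {
    stimulation_phase_at(p$p3_latency_ms, p$stim_freq_hz, o %% p$period_ms)
  }, numeric(1))
  tol <- 2 * pi * p$stim_freq_hz / cfg$sampling_rate_hz
  expect_lt(max(abs(ph - pi / 2)), tol + 1e-12)
  expect_true(all(s$onset_ms + cfg$stim_duration_ms <= 600 * 1000))
  expect_true(all(s$slack_ms >= 0 & s$slack_ms <= p$period_ms))

  # more trials at higher stimulation frequency on matched seeds
  n_hi <- nrow(schedule_during_block(stim_params(440, 6, duration_s = 600),
                                     cfg, seed = 5))
  n_lo <- nrow(schedule_during_block(stim_params(440, 1.5, duration_s = 600),
                                     cfg, seed = 5))
  expect_gt(n_hi, n_lo)
})

test_that("scheduled trial count matches the renewal-process expectation", {
  # cycle length = stimulus + E[ISI] + E[slack to next zero-cross] + wait;
  # slack for a uniform arrival in a period is ~T/2
  cfg <- tiny_cfg()
  p <- stim_params(440, 3, duration_s = 1200)
  counts <- vapply(1:20, function(s) {
    nrow(schedule_during_block(p, cfg, seed = s))
  }, numeric(1))
  expected <- 1200 * 1000 /
    (cfg$stim_duration_ms + mean(cfg$isi_range_ms) + p$period_ms / 2 +
       p$wait_ms)
  expect_lt(abs(mean(counts) - expected), 2)
})

test_that("stim and sham waveforms meet the amplitude contract", {
  p <- stim_params(440, 3, duration_s = 1200)
  wf <- generate_waveform(p, 1000)
  plateau <- wf$current_ma[wf$time_s >= 20 & wf$time_s <= 1180]
  expect_equal(max(plateau) - min(plateau), 1.0, tolerance = 1e-4)
  expect_lt(abs(mean(wf$current_ma)), 1e-3)        # no DC offset
  # ramps: amplitude grows linearly over the first 10 s
  head_env <- abs(wf$current_ma[wf$time_s <= 10])
  expect_lt(max(head_env - 0.5 * wf$time_s[wf$time_s <= 10] / 10), 1e-9)

  sham <- stim_params(440, 3, duration_s = 1200, mode = "sham")
  wfs <- generate_waveform(sham, 1000)
  expect_true(all(wfs$current_ma[wfs$time_s > 20] == 0))
  # fade-in reaches full amplitude near t = 10 s
  expect_gt(max(abs(wfs$current_ma[wfs$time_s <= 10])), 0.45)
  expect_error(generate_waveform(stim_params(440, 3), rate_hz = 5),
               class = "oddlock_parameter_error")
})

test_that("stim_params validates its invariants", {
  expect_error(stim_params(440, -1), class = "oddlock_parameter_error")
  expect_error(stim_params(440, 3, wait_ms = 400),
               class = "oddlock_parameter_error")
  p <- stim_params(440, 3)
  expect_equal(p$period_ms, 1000 / 3)
  expect_true(p$wait_ms >= 0 && p$wait_ms < p$period_ms)
})
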