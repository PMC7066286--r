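test_that("zero-phase filtering preserves passband and latencies", {
  # 3 Hz through an 8 Hz low-pass: amplitude within 1%
  rec <- constant_recording(function(t) sin(2 * pi * 3 * t), n_s = 20000)
  f <- filter_signal(rec, low_pass_hz = 8)
  mid <- 5000:15000
  expect_equal(max(abs(f$data[1, mid])), 1, tolerance = 0.01)

  # noiseless pulse: peak latency unchanged (zero-phase contract)
  rec2 <- constant_recording(function(t) exp(-(t - 5)^2 / (2 * 0.05^2)),
                             n_s = 10000)
  f2 <- filter_signal(rec2, low_pass_hz = 8)
  expect_equal(which.max(f2$data[1, ]), which.max(rec2$data[1, ]))

  # 16 Hz component attenuated >= 20 dB by an 8 Hz low-pass (FFT oracle)
  rec3 <- constant_recording(function(t) sin(2 * pi * 3 * t) +
                               sin(2 * pi * 16 * t), n_s = 20000)
  f3 <- filter_signal(rec3, low_pass_hz = 8)
  spec_in <- Mod(fft(rec3$data[1, ]))
  spec_out <- Mod(fft(f3$data[1, ]))
  bin16 <- which.min(abs((0:19999) * 1000 / 20000 - 16))
  atten_db <- 20 * log10(spec_in[bin16] / spec_out[bin16])
  expect_gte(atten_db, 20)

  expect_error(filter_signal(rec, low_pass_hz = 600),
               class = "oddlock_parameter_error")
  expect_error(filter_signal(rec, high_pass_hz = 10, low_pass_hz = 5),
               class = "oddlock_parameter_error")
})

test_that("epoching cuts the configured closed window with baseline zeroed", {
  ev <- tibble::tibble(sample = c(4000L, 6500L), code = c("target",
                                                          "standard"))
  rec <- constant_recording(function(t) rep(5, length(t)), n_s = 12000,
                            events = ev)
  ep <- epoch_recording(rec, window_ms = c(-3000, 4000),
                        baseline_ms = c(-50, 0))
  expect_equal(dim(ep$data), c(2, 3, 7001))
  # constant channel minus its baseline mean is identically zero
  expect_lt(max(abs(ep$data)), 1e-12)

  # event too close to the edge is dropped with a message
  ev2 <- tibble::tibble(sample = c(100L, 6000L), code = c("target",
                                                          "target"))
  rec2 <- constant_recording(function(t) rep(1, length(t)), n_s = 12000,
                             events = ev2)
  expect_message(ep2 <- epoch_recording(rec2), "Dropped 1")
  expect_equal(nrow(ep2$trials), 1)
  expect_equal(ep2$n_dropped_edge, 1)

  expect_error(epoch_recording(rec, codes = "nonexistent"),
               class = "oddlock_empty_set_error")
})

test_that("blink-trial rejection follows the amplitude + uniformity rule", {
  # epochs built directly: 2 trials, template blink on all channels
  cfg <- clean_cfg(n_trials = 6)
  sched <- generate_trial_sequence(cfg = cfg)
  rec <- synthesize_eeg(sched, cfg)
  ep <- epoch_recording(rec)
  blink <- 300 * exp(-(seq(-200, 200) / 80)^2)
  at <- function(ms) which(ep$times >= ms - 200 & ep$times <= ms + 200)
  n_ch <- dim(ep$data)[2]
  ep$data[1, , at(500)] <- ep$data[1, , at(500)] +
    matrix(rep(blink, each = n_ch), nrow = n_ch)
  ep$data[2, , at(-500)] <- ep$data[2, , at(-500)] +
    matrix(rep(blink, each = n_ch), nrow = n_ch)
  out <- reject_blink_trials(ep, amp_threshold_uv = 100)
  expect_true(out$trials$rejected[1])         # inside 0-1 s: rejected
  expect_false(out$trials$rejected[2])        # at -500 ms: retained
  expect_equal(out$trials$rejection_reason[1], "blink")
  # retained trials' samples are untouched
  expect_identical(out$data[2, , ], ep$data[2, , ])
})

test_that("rejected fraction tracks the generator blink probability", {
  cfg <- tiny_cfg(n_trials = 120, blink_prob = 0.12, seed = 77)
  sched <- generate_trial_sequence(cfg = cfg)
  rec <- synthesize_eeg(sched, cfg)
  ep <- reject_blink_trials(epoch_recording(rec))
  frac <- mean(ep$trials$rejected)
  se <- sqrt(0.12 * 0.88 / 120)
  expect_lt(abs(frac - 0.12), 3 * se + 0.02)
})

test_that("average reference zeroes the channel mean and is idempotent", {
  cfg <- tiny_cfg(n_trials = 6)
  sched <- generate_trial_sequence(cfg = cfg)
  ep <- epoch_recording(synthesize_eeg(sched, cfg))
  ar <- average_reference(ep)
  means <- apply(ar$data, c(1, 3), mean)
  expect_lt(max(abs(means)), 1e-9)
  # idempotence
  ar2 <- average_reference(ar)
  expect_equal(ar2$data, ar$data, tolerance = 1e-12)
  # inter-channel differences preserved exactly
  expect_equal(ar$data[1, 1, ] - ar$data[1, 2, ],
               ep$data[1, 1, ] - ep$data[1, 2, ], tolerance = 1e-12)
  # single channel refused
  ep1 <- ep
  ep1$data <- ep1$data[, 1, , drop = FALSE]
  expect_error(average_reference(ep1), class = "oddlock_parameter_error")
})

test_that("filtering commutes with epoching away from record edges", {
  cfg <- tiny_cfg(n_trials = 8, seed = 12)
  sched <- generate_trial_sequence(cfg = cfg)
  rec <- synthesize_eeg(sched, cfg)
  a <- epoch_recording(filter_signal(rec, low_pass_hz = 20))
  b_rec <- rec
  # filtering the continuous record then epoching is the package's fixed
  # operation order; epoch extraction itself must not change samples
  raw_ep <- epoch_recording(b_rec, baseline_ms = NULL)
  ev <- rec$events[rec$events$code %in% c("standard", "target"), ]
  k <- raw_ep$trials$event_sample[1]
  expect_equal(raw_ep$data[1, , ], rec$data[, (k - 3000):(k + 4000)])
  expect_equal(dim(a$data)[3], 7001)
})
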