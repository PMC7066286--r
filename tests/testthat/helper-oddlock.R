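# Small fixtures shared across test files. Everything is generated in code;
# sizes are kept small so the whole suite stays fast.

# a compact session: few trials, few channels, default SNR
tiny_cfg <- function(n_trials = 30, n_channels = 4, seed = 42, ...) {
  sim_config(n_trials = n_trials, n_channels = n_channels, seed = seed, ...)
}

# a noiseless, blink-free session: the ERO is the only signal
clean_cfg <- function(n_trials = 10, seed = 7, ...) {
  sim_config(n_trials = n_trials, n_channels = 4, noise_rms_uv = 0,
             blink_prob = 0, seed = seed, ...)
}

# recording with a constructed signal on every channel
constant_recording <- function(fun, n_ch = 3, n_s = 10000, sfreq = 1000,
                               events = NULL) {
  t <- (seq_len(n_s) - 1) / sfreq
  data <- matrix(rep(fun(t), n_ch), nrow = n_ch, byrow = TRUE)
  labels <- c("Pz", "Cz", "Fz", "Fp1", "Oz")[seq_len(n_ch)]
  if (is.null(events)) events <- oddlock::empty_events()
  eeg_recording(data, sfreq, labels, events)
}

# exhaustive-permutation oracle for the rank-sum test: p-value of the
# observed rank sum of x among all C(n1+n2, n1) assignments
perm_ranksum_p <- function(x, y, tail) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  all_w <- apply(utils::combn(length(pooled), n1), 2,
                 function(idx) sum(r[idx]))
  switch(tail,
         "greater" = mean(all_w >= w_obs),
         "less" = mean(all_w <= w_obs),
         "two-sided" = {
           mu <- n1 * (length(pooled) + 1) / 2
           min(1, 2 * min(mean(all_w >= w_obs), mean(all_w <= w_obs)))
         })
}

# hand application of the Benjamini-Hochberg step-up rule
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# moments of a normal truncated to (lo, hi)
truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  lam <- (dnorm(a) - dnorm(b)) / z
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z - lam^2)
  list(mean = m, sd = sqrt(v))
}
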