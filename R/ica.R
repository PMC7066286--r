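# Compact symmetric FastICA (tanh contrast, eigen whitening).
# x: channels x samples, assumed roughly zero-mean per channel.
# Returns list(S = components x samples, A = mixing channels x components,
# W = unmixing components x channels).
fastica_decompose <- function(x, n_comp = nrow(x), max_iter = 200,
                              tol = 1e-6, seed = 1L) {
  x <- x - rowMeans(x)
  n <- ncol(x)
  cv <- tcrossprod(x) / n
  eg <- eigen(cv, symmetric = TRUE)
  keep <- which(eg$values > max(eg$values) * 1e-9)[seq_len(
    min(n_comp, sum(eg$values > max(eg$values) * 1e-9)))]
  K <- diag(1 / sqrt(eg$values[keep]), length(keep)) %*%
    t(eg$vectors[, keep, drop = FALSE])        # whitening, comps x channels
  z <- K %*% x
  p <- nrow(z)
  withr::with_seed(seed, {
    W <- matrix(rnorm(p * p), p, p)
  })
  sym_orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_orth(W)
  for (it in seq_len(max_iter)) {
    wz <- W %*% z
    g <- tanh(wz)
    gp <- 1 - g^2
    W1 <- g %*% t(z) / n - diag(rowMeans(gp)) %*% W
    W1 <- sym_orth(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  unmix <- W %*% K                              # comps x channels
  A <- MASS_ginv(unmix)                         # mixing, channels x comps
  list(S = unmix %*% x, A = A, W = unmix)
}

# Moore-Penrose pseudo-inverse via SVD (channels x comps for a comps x
# channels unmixing matrix).
MASS_ginv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > max(s$d) * tol
  s$v[, pos, drop = FALSE] %*%
    diag(1 / s$d[pos], sum(pos)) %*% t(s$u[, pos, drop = FALSE])
}

#' Remove blink components from epochs by ICA
#'
#' Decomposes the retained epochs (channels x concatenated samples) with
#' FastICA, flags components whose time course correlates with the EOG proxy
#' channel beyond `corr_threshold`, and removes them — unless the
#' trial-averaged component time course peaks within the P300 window
#' (300-600 ms post-onset), in which case the component is protected so that
#' no P300-carrying source is discarded. The cleaned mixture is
#' reconstructed in channel space.
#'
#' @param ep An `epoch_set`.
#' @param eog_label Channel serving as the ocular reference (default `"Fp1"`;
#'   frontal-pole channels carry blinks almost undiluted).
#' @param corr_threshold Absolute correlation above which a component counts
#'   as ocular (default 0.7).
#' @param p300_window_ms Protection window for components with
#'   stimulus-locked activity (default `c(300, 600)`).
#' @param seed Seed for the FastICA initialization.
#'
#' @return The `epoch_set` with the flagged components removed;
#'   `$ica_removed` holds the number of removed components.
#' @export
clean_components <- function(ep, eog_label = "Fp1", corr_threshold = 0.7,
                             p300_window_ms = c(300, 600), seed = 1L) {
  if (!eog_label %in% ep$channels) {
    abort(sprintf("EOG channel `%s` not present.", eog_label),
          class = "oddlock_parameter_error")
  }
  keep <- retained_trials(ep)
  n_tr <- length(keep)
  n_ch <- dim(ep$data)[2]
  n_t <- dim(ep$data)[3]
  if (n_tr * n_t < 20 * n_ch) {
    abort("Too few retained samples for a stable decomposition.",
          class = "oddlock_decomposition_error")
  }
  # channels x (trials * time)
  x <- matrix(aperm(ep$data[keep, , , drop = FALSE], c(2, 3, 1)),
              nrow = n_ch)
  mu <- rowMeans(x)
  # estimate the unmixing on a time-decimated copy (the statistics of the
  # sources do not change), then apply it to the full data
  dec <- fastica_decompose((x - mu)[, seq(1, ncol(x), by = 4), drop = FALSE],
                           seed = seed)
  dec$S <- dec$W %*% (x - mu)
  eog <- x[match(eog_label, ep$channels), ] - mu[match(eog_label,
                                                       ep$channels)]
  r <- as.numeric(abs(cor(t(dec$S), eog)))
  cand <- which(r > corr_threshold)
  if (length(cand) > 0) {
    # P300 guard: protect components whose trial-averaged |time course|
    # peaks inside the P300 window
    protected <- vapply(cand, function(ci) {
      tc <- matrix(dec$S[ci, ], nrow = n_t)    # time x trials
      avg <- rowMeans(tc)
      pk <- ep$times[which.max(abs(avg))]
      pk >= p300_window_ms[1] && pk <= p300_window_ms[2]
    }, logical(1))
    cand <- cand[!protected]
  }
  if (length(cand) > 0) {
    S <- dec$S
    S[cand, ] <- 0
    x_clean <- dec$A %*% S + mu
    ep$data[keep, , ] <- aperm(array(x_clean, dim = c(n_ch, n_t, n_tr)),
                               c(3, 1, 2))
  }
  ep$ica_removed <- length(cand)
  ep
}
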