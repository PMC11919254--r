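# Independent reference implementations used to cross-check the package.

# Explicit ridge solve: z-score the design with scale(), normalize the
# scatter to a correlation matrix, solve per channel, map weights back.
ridge_oracle <- function(X, Y, lambda) {
  n <- nrow(X)
  Xz <- scale(X)
  sdv <- attr(Xz, "scaled:scale")
  sdv[sdv == 0] <- 1
  Xz[, attr(Xz, "scaled:scale") == 0] <- 0
  Yc <- sweep(Y, 2, colMeans(Y))
  S <- crossprod(Xz) / (n - 1)
  B <- crossprod(Xz, Yc) / (n - 1)
  wz <- solve(S + diag(lambda, ncol(X)), B)
  t(wz / sdv)
}

# Step-up Benjamini-Hochberg by direct enumeration over k: the rejection set
# is the p-values at or below p_(k*) where k* is the largest k with
# p_(k) <= k * q / m.
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ks <- which(ps <= seq_len(m) * q / m)
  if (length(ks) == 0) return(rep(FALSE, m))
  p <- p <= ps[max(ks)]
  p
}

# Naive shift-and-stack lagged design for comparison with
# build_design_matrix.
design_oracle <- function(v, rate, lag_min, lag_max) {
  n <- length(v)
  shift0 <- as.integer(ceiling(lag_min * rate - 1e-9))
  n_lags <- as.integer(floor(lag_max * rate + 1e-9)) - shift0 + 1L
  X <- matrix(0, n, n_lags)
  for (j in seq_len(n_lags)) {
    s <- shift0 + j - 1L
    for (t in seq_len(n)) {
      src <- t - s
      if (src >= 1 && src <= n) X[t, j] <- v[src]
    }
  }
  X
}

# Short white-noise-like test envelope.
rand_env <- function(n, rate = 512, seed = 1) {
  set.seed(seed)
  envelope_series(abs(rnorm(n)), rate, "onset")
}

rand_eeg <- function(n, labels = c("Cz", "Fz"), rate = 512, seed = 2,
                     reference = "linked_mastoids") {
  set.seed(seed)
  eeg_recording(matrix(rnorm(n * length(labels)), length(labels)),
                rate, labels, reference)
}

scalp_labels <- function() setdiff(eeg_channels(), c("M1", "M2"))

# Welch-style log-log PSD slope of a waveform.
psd_slope <- function(w, f_lo = 1, f_hi = NULL) {
  if (is.null(f_hi)) f_hi <- w$rate * 0.45
  p <- stats::spec.pgram(stats::ts(w$samples, frequency = w$rate),
                         spans = 65, plot = FALSE, taper = 0)
  keep <- p$freq > f_lo & p$freq < f_hi
  unname(coef(stats::lm(log(p$spec[keep]) ~ log(p$freq[keep])))[2])
}

# Steady-state amplitude gain (dB) of a single-channel filter operation at
# frequency f, excluding edge transients.
tone_gain_db <- function(fun, f, rate = 1024, dur = 10) {
  t <- (0:(dur * rate - 1)) / rate
  x <- sin(2 * pi * f * t)
  rec <- eeg_recording(matrix(x, 1), rate, "Cz", "raw")
  out <- fun(rec)
  mid_in <- (3 * rate):(7 * rate)
  mid_out <- (3 * out$rate):(7 * out$rate)
  20 * log10(sd(out$data[1, mid_out]) / sd(x[mid_in]))
}
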