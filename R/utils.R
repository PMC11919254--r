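#' @importFrom Rcpp sourceCpp
#' @useDynLib speechtrack, .registration = TRUE
NULL

#' Root-mean-square amplitude
#'
#' @param x Numeric vector (or a [waveform]).
#' @return RMS of the samples.
#' @export
rms <- function(x) {
  if (inherits(x, "waveform")) x <- x$samples
  sqrt(mean(x^2))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.  All stochastic operations in the package go
# through this so that results are reproducible from a manifest of seeds.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and one or more indices, staying
# within the positive 32-bit integer range.
child_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (i in idx) s <- (s * 69069 + i) %% 2147483629
  as.integer(s)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Zero-phase application of a linear-phase FIR filter: convolve (with zero
# padding on both sides) and remove the integer group delay so that features
# stay time-locked.
fir_apply <- function(x, taps) {
  n <- length(x)
  L <- length(taps)
  delay <- (L - 1L) %/% 2L
  z <- c(numeric(L - 1L), x, numeric(L - 1L))
  y <- stats::filter(z, taps, method = "convolution", sides = 1L)
  as.numeric(y[(L - 1L) + (delay + 1L):(delay + n)])
}

# Kaiser-window FIR design via signal::fir1.  `n_taps` must be odd so the
# group delay is an integer number of samples.
fir_design <- function(n_taps, cutoff_hz, rate, type = c("low", "high"),
                       window = c("kaiser", "hann"), beta = 5.653) {
  type <- match.arg(type)
  window <- match.arg(window)
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  w <- switch(window,
    kaiser = signal::kaiser(n_taps, beta),
    hann   = signal::hanning(n_taps)
  )
  taps <- as.numeric(signal::fir1(n_taps - 1L, cutoff_hz / (rate / 2), type, w))
  # a high-pass must null DC exactly; distribute the residual tap sum
  if (type == "high") taps <- taps - sum(taps) / n_taps
  taps
}
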