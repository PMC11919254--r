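#' Envelope time series
#'
#' Single-channel envelope container used as the TRF regressor.
#'
#' @param values Numeric vector; must be non-negative for `kind = "onset"`.
#' @param rate Sampling rate in Hz.
#' @param kind `"amplitude"` or `"onset"`.
#' @return An object of class `envelope_series`.
#' @export
envelope_series <- function(values, rate, kind = c("amplitude", "onset")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop_invalid("envelope values must be finite")
  if (kind == "onset" && any(values < 0)) {
    stop_invalid("onset envelope must be non-negative")
  }
  structure(list(values = values, rate = as.numeric(rate), kind = kind),
            class = "envelope_series")
}

#' @export
print.envelope_series <- function(x, ...) {
  cat(sprintf("<envelope_series:%s> %d samples @ %g Hz\n",
              x$kind, length(x$values), x$rate))
  invisible(x)
}

#' ERB-number scale
#'
#' `erb_number()` maps frequency (Hz) to the ERB-number scale
#' `ERBn(f) = 21.4 log10(0.00437 f + 1)`; `erb_bandwidth()` gives the
#' equivalent rectangular bandwidth of the auditory filter centered at `f`.
#'
#' @param f Frequency in Hz.
#' @return ERB-number (dimensionless) or bandwidth (Hz).
#' @export
erb_number <- function(f) 21.4 * log10(0.00437 * f + 1)

#' @rdname erb_number
#' @export
erb_bandwidth <- function(f) 24.7 * (4.37 * f / 1000 + 1)

erb_number_inv <- function(e) (10^(e / 21.4) - 1) / 0.00437

#' Filter center frequencies evenly spaced on the ERB scale
#'
#' @param n Number of filters (>= 2).
#' @param f_lo,f_hi Band edges in Hz (`0 < f_lo < f_hi`); both are included
#'   as the first and last center.
#' @return Strictly increasing numeric vector of length `n` (Hz).
#' @examples
#' erb_center_frequencies(30, 20, 10000)
#' @export
erb_center_frequencies <- function(n, f_lo, f_hi) {
  if (n < 2L) stop_invalid("need at least 2 filters")
  if (!(f_lo > 0 && f_lo < f_hi)) stop_invalid("need 0 < f_lo < f_hi")
  erb_number_inv(seq(erb_number(f_lo), erb_number(f_hi), length.out = n))
}

#' Cochleagram parameters
#'
#' Settings of the simple auditory-periphery model: 30 gammatone filters with
#' centers evenly spaced on the ERB scale, power-law compression with exponent
#' 0.6 emulating inner-ear compression, and a 40 Hz fourth-order Butterworth
#' low-pass on the band-averaged envelope.
#'
#' @param n_filters Number of auditory filters.
#' @param compression_exponent Power-law exponent in (0, 1].
#' @param f_lo,f_hi Filterbank band edges (Hz).
#' @param envelope_lp_hz Envelope low-pass cutoff (Hz).
#' @param lp_order Butterworth order of the envelope low-pass.
#' @param zero_phase Apply the envelope low-pass forward-backward?
#' @return A list of class `cochleagram_params`.
#' @export
cochleagram_params <- function(n_filters = 30L, compression_exponent = 0.6,
                               f_lo = 20, f_hi = 10000, envelope_lp_hz = 40,
                               lp_order = 4L, zero_phase = TRUE) {
  if (!(compression_exponent > 0 && compression_exponent <= 1)) {
    stop_invalid("compression_exponent must be in (0, 1]")
  }
  if (n_filters < 2L) stop_invalid("n_filters must be >= 2")
  if (!(f_lo < f_hi)) stop_invalid("need f_lo < f_hi")
  structure(list(n_filters = as.integer(n_filters),
                 compression_exponent = compression_exponent,
                 f_lo = f_lo, f_hi = f_hi,
                 envelope_lp_hz = envelope_lp_hz,
                 lp_order = as.integer(lp_order),
                 zero_phase = isTRUE(zero_phase)),
            class = "cochleagram_params")
}

# Sub-band Hilbert envelopes through a frequency-sampled gammatone filterbank.
# The analytic signal of each band is obtained in one pass: the input spectrum
# is multiplied by the (zero-phase) fourth-order gammatone magnitude response
# on the positive frequencies only, and the envelope is the modulus of the
# inverse FFT.  Linear in the input, so compression acts homogeneously.
#' Auditory-periphery cochleagram
#'
#' Decomposes a waveform into compressed sub-band envelopes: gammatone
#' filters at ERB-spaced centers, Hilbert-magnitude envelopes, and pointwise
#' power-law compression (`env^0.6` by default).
#'
#' @param wave A [waveform] with `rate >= 2 * f_hi`.
#' @param params A [cochleagram_params] object.
#' @return A list of class `cochleagram`: `bands` (n_filters x n matrix of
#'   compressed envelopes), `centers` (Hz), `rate`, `params`.
#' @export
cochleogram <- function(wave, params = cochleagram_params()) {
  stopifnot(inherits(wave, "waveform"))
  if (wave$rate < 2 * params$f_hi) {
    stop_invalid("sampling rate %g Hz too low for f_hi = %g Hz",
                 wave$rate, params$f_hi)
  }
  x <- wave$samples
  n <- length(x)
  centers <- erb_center_frequencies(params$n_filters, params$f_lo, params$f_hi)
  X <- stats::fft(x)
  half <- n %/% 2L
  pos_idx <- seq_len(half + 1L)                 # DC .. Nyquist (or last bin)
  f_pos <- (pos_idx - 1L) * wave$rate / n
  analytic_w <- rep(2, length(pos_idx))
  analytic_w[1L] <- 1
  if (n %% 2L == 0L) analytic_w[length(pos_idx)] <- 1
  bands <- matrix(0, params$n_filters, n)
  for (b in seq_len(params$n_filters)) {
    bw <- 1.019 * erb_bandwidth(centers[b])
    H <- (1 + ((f_pos - centers[b]) / bw)^2)^(-2)   # 4th-order gammatone magnitude
    spec <- complex(real = numeric(n), imaginary = numeric(n))
    spec[pos_idx] <- X[pos_idx] * H * analytic_w
    env <- Mod(stats::fft(spec, inverse = TRUE) / n)
    bands[b, ] <- env^params$compression_exponent
  }
  structure(list(bands = bands, centers = centers, rate = wave$rate,
                 params = params),
            class = "cochleagram")
}

# Band-average the cochleagram and apply the 40 Hz Butterworth low-pass
# (zero-phase by default), still at the audio rate.
smoothed_mean_envelope <- function(coch) {
  m <- colMeans(coch$bands)
  bf <- signal::butter(coch$params$lp_order,
                       coch$params$envelope_lp_hz / (coch$rate / 2), "low")
  if (coch$params$zero_phase) {
    as.numeric(signal::filtfilt(bf, m))
  } else {
    as.numeric(signal::filter(bf, m))
  }
}

# Band-limited interpolation onto the EEG sampling grid.  The envelope is
# low-passed at 40 Hz, far below the 256 Hz Nyquist of the 512 Hz target, so
# linear interpolation on the time grid is accurate and delay-free.
resample_envelope <- function(values, rate_in, rate_out) {
  if (rate_in == rate_out) return(values)
  n_out <- round(length(values) * rate_out / rate_in)
  t_out <- (seq_len(n_out) - 1L) / rate_out
  stats::approx(x = (seq_along(values) - 1L) / rate_in, y = values,
                xout = t_out, rule = 2)$y
}

#' Amplitude envelope of a speech waveform
#'
#' The band-averaged, compressed, 40 Hz low-passed cochlear envelope,
#' resampled to the EEG rate.  Small negative ripples introduced by the
#' low-pass filter are clipped at zero.
#'
#' @param wave A [waveform] of clear (unmasked) speech.
#' @param params A [cochleagram_params] object.
#' @param eeg_rate Target sampling rate (Hz); `NULL` keeps the audio rate.
#' @return An [envelope_series] of kind `"amplitude"`.
#' @export
amplitude_envelope <- function(wave, params = cochleagram_params(),
                               eeg_rate = 512) {
  m <- smoothed_mean_envelope(cochleogram(wave, params))
  m <- pmax(m, 0)
  if (!is.null(eeg_rate)) {
    m <- resample_envelope(m, wave$rate, eeg_rate)
    rate <- eeg_rate
  } else {
    rate <- wave$rate
  }
  envelope_series(m, rate, "amplitude")
}

#' Amplitude-onset envelope of a speech waveform
#'
#' First derivative (first difference scaled by the sampling rate) of the
#' smoothed cochlear envelope with negative values set to zero, emphasizing
#' acoustic onsets, then resampled to the EEG rate.  The derivative and
#' rectification are computed at the audio rate, before resampling.
#'
#' @inheritParams amplitude_envelope
#' @return An [envelope_series] of kind `"onset"`, non-negative everywhere.
#' @export
onset_envelope <- function(wave, params = cochleagram_params(),
                           eeg_rate = 512) {
  m <- smoothed_mean_envelope(cochleogram(wave, params))
  d <- c(0, diff(m)) * wave$rate
  d <- pmax(d, 0)
  if (!is.null(eeg_rate)) {
    d <- resample_envelope(d, wave$rate, eeg_rate)
    rate <- eeg_rate
  } else {
    rate <- wave$rate
  }
  envelope_series(pmax(d, 0), rate, "onset")
}
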