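#' Construct an SNR condition grid
#'
#' The speech-clarity conditions of a masking experiment: a descending ladder
#' of signal-to-noise ratios, optionally preceded by a clear (no-masker)
#' condition.  The default grid runs from +30 dB down in 21 steps of 1.6 dB,
#' reaching -2 dB SNR.
#'
#' @param start_db Highest SNR (dB).
#' @param step_db Step size between neighboring levels (dB, positive).
#' @param n_levels Number of SNR levels.
#' @param include_clear Include a clear-speech condition alongside the grid?
#' @return A tibble with columns `condition` ("clear" or "snr_<level>"),
#'   `snr_db` (`NA` for clear), ordered from clear/highest SNR downwards.
#' @examples
#' condition_grid()
#' @export
condition_grid <- function(start_db = 30, step_db = 1.6, n_levels = 21L,
                           include_clear = TRUE) {
  stopifnot(step_db > 0, n_levels >= 1L)
  levels <- start_db - step_db * (seq_len(n_levels) - 1L)
  grid <- tibble::tibble(
    condition = sprintf("snr_%+.1f", levels),
    snr_db = levels
  )
  if (include_clear) {
    grid <- dplyr::bind_rows(
      tibble::tibble(condition = "clear", snr_db = NA_real_),
      grid
    )
  }
  grid
}

# Scale factor applied to a masker so that speech/masker RMS ratio hits the
# requested SNR: 20*log10(rms(speech) / (k * rms(masker))) = snr_db.
masker_scale <- function(speech_rms, masker_rms, snr_db) {
  (speech_rms / masker_rms) * 10^(-snr_db / 20)
}

#' Mix speech and masker at a given SNR
#'
#' The masker is scaled so that the broadband RMS ratio of speech to masker
#' equals `snr_db`, then added to the speech.  SNR is defined on the full
#' speech duration with no spectral or speech-activity weighting.  Maskers
#' longer than the speech are cropped from a seeded random start offset;
#' shorter maskers are an error (no looping).
#'
#' @param speech,masker [waveform]s with equal sampling rates and nonzero RMS.
#' @param snr_db Signal-to-noise ratio in dB.
#' @param seed Seed for the random crop offset of an over-long masker.
#' @return A [waveform] of the same length as `speech`.
#' @export
mix_at_snr <- function(speech, masker, snr_db, seed = 1L) {
  stopifnot(inherits(speech, "waveform"), inherits(masker, "waveform"))
  if (speech$rate != masker$rate) {
    stop_invalid("speech and masker rates differ (%g vs %g Hz)",
                 speech$rate, masker$rate)
  }
  n <- length(speech$samples)
  if (length(masker$samples) < n) {
    stop_invalid("masker (%d samples) shorter than speech (%d samples)",
                 length(masker$samples), n)
  }
  if (length(masker$samples) > n) {
    offset <- with_seed(seed, sample.int(length(masker$samples) - n + 1L, 1L))
    masker_samp <- masker$samples[offset:(offset + n - 1L)]
  } else {
    masker_samp <- masker$samples
  }
  rs <- rms(speech$samples)
  rm_ <- rms(masker_samp)
  if (rs == 0) stop_invalid("speech has zero RMS")
  if (rm_ == 0) stop_invalid("masker has zero RMS")
  k <- masker_scale(rs, rm_, snr_db)
  waveform(speech$samples + k * masker_samp, speech$rate)
}

#' Normalize a speech+masker mixture
#'
#' Two level-normalization schemes are used when presenting mixtures across
#' SNR conditions:
#' \describe{
#'   \item{`mixture_rms`}{the whole mixture is scaled to `target_rms`, so the
#'     speech level within the mixture drops as SNR decreases;}
#'   \item{`speech_rms`}{the mixture is returned unchanged — the speech was
#'     fixed at `target_rms` upstream, so overall level grows as SNR
#'     decreases.}
#' }
#'
#' @param mix A [waveform] mixture.
#' @param normalization `"mixture_rms"` or `"speech_rms"`.
#' @param target_rms Reference RMS (must be positive).
#' @return A [waveform].
#' @export
normalize_mixture <- function(mix, normalization = c("mixture_rms", "speech_rms"),
                              target_rms = 0.05) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(mix, "waveform"))
  if (target_rms <= 0) stop_invalid("target_rms must be positive")
  if (normalization == "speech_rms") return(mix)
  r <- rms(mix$samples)
  if (r == 0) stop_invalid("cannot RMS-normalize an all-zero mixture")
  waveform(mix$samples * (target_rms / r), mix$rate)
}

#' Spectrally matched stationary noise
#'
#' Noise with the long-term magnitude spectrum of a speech signal: the FFT
#' magnitude of the input is kept bin-for-bin while phases are drawn uniformly
#' on (-pi, pi], with Hermitian symmetry enforced and the DC and Nyquist bins
#' kept real so the output is a real time series.
#'
#' @param speech A [waveform] (length >= 2).
#' @param seed Integer seed; identical `(speech, seed)` give identical noise.
#' @return A [waveform] of the same length and rate as `speech`.
#' @export
spectrally_matched_noise <- function(speech, seed = 1L) {
  stopifnot(inherits(speech, "waveform"))
  x <- speech$samples
  n <- length(x)
  if (n < 2L) stop_invalid("need at least 2 samples to randomize phase")
  mag <- Mod(stats::fft(x))
  half <- (n %/% 2L)
  n_free <- if (n %% 2L == 0L) half - 1L else half
  phases <- with_seed(seed, stats::runif(n_free, -pi, pi))
  ph <- numeric(n)
  if (n_free > 0L) {
    ph[2L:(n_free + 1L)] <- phases
    ph[n:(n - n_free + 1L)] <- -phases
  }
  # ph[1] (DC) and, for even n, ph[half+1] (Nyquist) stay 0: bins remain real.
  spec <- mag * exp(1i * ph)
  waveform(Re(stats::fft(spec, inverse = TRUE)) / n, speech$rate)
}

#' Synthesize white or pink noise
#'
#' Both noises are generated in the frequency domain with seeded random
#' phases: white noise has a flat magnitude spectrum, pink noise has power
#' proportional to 1/f (a log-log spectral slope of -1).
#'
#' @param kind `"white"` or `"pink"`.
#' @param n Number of samples (>= 2).
#' @param rate Sampling rate in Hz.
#' @param seed Integer seed.
#' @return A zero-mean, unit-RMS [waveform].
#' @export
synth_noise <- function(kind = c("white", "pink"), n, rate, seed = 1L) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (n < 2L) stop_invalid("need n >= 2 samples")
  half <- n %/% 2L
  n_free <- if (n %% 2L == 0L) half - 1L else half
  phases <- with_seed(seed, stats::runif(n_free, -pi, pi))
  freq_bins <- seq_len(n_free)          # bins 2..n_free+1, f = bin * rate / n
  mag <- switch(kind,
    white = rep(1, n_free),
    pink  = 1 / sqrt(freq_bins)         # amplitude 1/sqrt(f) -> power 1/f
  )
  spec <- complex(real = numeric(n), imaginary = numeric(n))
  spec[2L:(n_free + 1L)] <- mag * exp(1i * phases)
  spec[n:(n - n_free + 1L)] <- Conj(spec[2L:(n_free + 1L)])
  # DC zero -> zero mean; Nyquist (even n) left at zero.
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x <- x / rms(x)
  waveform(x, rate)
}

#' Sum talker streams into multi-talker babble
#'
#' Each stream is RMS-equalized, then the streams are summed and the result
#' is normalized to unit RMS.  Twelve talkers (six male, six female, in
#' practice) give the standard "12-talker babble" masker: recognizably
#' speech-like but unintelligible.
#'
#' @param talkers List of [waveform]s with equal rates, each at least
#'   `n_samples` long.
#' @param n_samples Output length in samples (default: shortest talker).
#' @param n_required Minimum number of streams (default 12).
#' @return A unit-RMS [waveform].
#' @export
make_babble <- function(talkers, n_samples = NULL, n_required = 12L) {
  if (length(talkers) < n_required) {
    stop_invalid("need at least %d talker streams, got %d",
                 n_required, length(talkers))
  }
  stopifnot(all(vapply(talkers, inherits, logical(1), "waveform")))
  rates <- vapply(talkers, function(w) w$rate, numeric(1))
  if (length(unique(rates)) != 1L) stop_invalid("talker rates differ")
  if (is.null(n_samples)) {
    n_samples <- min(vapply(talkers, function(w) length(w$samples), integer(1)))
  }
  lens <- vapply(talkers, function(w) length(w$samples), integer(1))
  if (any(lens < n_samples)) {
    stop_invalid("all talker streams must be at least %d samples", n_samples)
  }
  acc <- numeric(n_samples)
  for (w in talkers) {
    seg <- w$samples[seq_len(n_samples)]
    acc <- acc + seg / rms(seg)
  }
  waveform(acc / rms(acc), rates[1])
}

#' Build one masked stimulus for a condition
#'
#' Convenience wrapper: scales speech to `target_rms`, mixes the masker at the
#' requested SNR, and applies the chosen normalization scheme.  A final fixed
#' reference RMS stands in for the constant presentation level of a
#' loudspeaker/headphone calibration; absolute SPL is not modelled.
#'
#' @inheritParams mix_at_snr
#' @inheritParams normalize_mixture
#' @return A [waveform].
#' @export
make_stimulus <- function(speech, masker, snr_db,
                          normalization = c("mixture_rms", "speech_rms"),
                          target_rms = 0.05, seed = 1L) {
  normalization <- match.arg(normalization)
  speech <- waveform(speech$samples * (target_rms / rms(speech$samples)),
                     speech$rate)
  if (is.na(snr_db)) return(speech)
  mix <- mix_at_snr(speech, masker, snr_db, seed = seed)
  normalize_mixture(mix, normalization, target_rms)
}
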