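#' Suppress line noise with an elliptic notch
#'
#' Minimal-order elliptic band-stop around 60 Hz (stopband 59.5-60.5 Hz,
#' at least 80 dB suppression; passband below 55 and above 65 Hz within
#' 1 dB), applied forward-backward so the net filter is zero-phase.
#'
#' @param rec An [eeg_recording] with `rate > 121` Hz.
#' @param line_hz Line frequency to suppress (Hz).
#' @return The filtered [eeg_recording].
#' @export
notch_60hz <- function(rec, line_hz = 60) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$rate <= 2 * line_hz + 1) {
    stop_invalid("rate %g Hz too low to notch %g Hz", rec$rate, line_hz)
  }
  flt <- signal::ellip(4, 0.25, 80,
                       c(line_hz - 3, line_hz + 3) / (rec$rate / 2),
                       type = "stop")
  flt$b <- flt$b / (sum(flt$b) / sum(flt$a))   # pin DC gain to exactly 1
  out <- rec
  for (ch in seq_len(nrow(rec$data))) {
    out$data[ch, ] <- signal::filtfilt(flt, rec$data[ch, ])
  }
  out
}

#' Re-reference to linked mastoids
#'
#' Subtracts the mean of the left and right mastoid channels from every scalp
#' channel.  The mastoid channels are dropped from the output; re-referencing
#' an already re-referenced recording is an error.
#'
#' @param rec An [eeg_recording] with `reference = "raw"`.
#' @param mastoids Labels of the two mastoid channels.
#' @return An [eeg_recording] of the scalp channels, `reference =
#'   "linked_mastoids"`.
#' @export
rereference_mastoids <- function(rec, mastoids = c("M1", "M2")) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$reference != "raw") {
    stop_invalid("recording is already re-referenced (%s)", rec$reference)
  }
  missing <- setdiff(mastoids, rec$labels)
  if (length(missing) > 0L) {
    stop_invalid("mastoid channel(s) missing: %s", paste(missing, collapse = ", "))
  }
  ref <- colMeans(rec$data[mastoids, , drop = FALSE])
  scalp <- setdiff(rec$labels, mastoids)
  dat <- sweep(rec$data[scalp, , drop = FALSE], 2, ref)
  eeg_recording(dat, rec$rate, scalp, "linked_mastoids", rec$artifact_mask)
}

#' Band-limit EEG with linear-phase FIR filters
#'
#' A 0.7 Hz high-pass (2449 taps, Hann window) followed by a 22 Hz low-pass
#' (211 taps, Kaiser window), both applied with exact group-delay
#' compensation.  The tap counts are defined at 1024 Hz; at other rates they
#' are rescaled proportionally with a warning.
#'
#' @param rec An [eeg_recording].
#' @param hp_hz,lp_hz High-/low-pass cutoffs (Hz).
#' @param hp_taps,lp_taps Filter lengths at 1024 Hz.
#' @return The filtered [eeg_recording].
#' @export
band_limit <- function(rec, hp_hz = 0.7, lp_hz = 22,
                       hp_taps = 2449L, lp_taps = 211L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$rate != 1024) {
    scale <- rec$rate / 1024
    hp_taps <- as.integer(round(hp_taps * scale))
    lp_taps <- as.integer(round(lp_taps * scale))
    warning(sprintf("rate %g Hz != 1024 Hz; FIR lengths rescaled to %d/%d taps",
                    rec$rate, hp_taps, lp_taps))
  }
  hp <- fir_design(hp_taps, hp_hz, rec$rate, "high", "hann")
  lp <- fir_design(lp_taps, lp_hz, rec$rate, "low", "kaiser")
  out <- rec
  for (ch in seq_len(nrow(rec$data))) {
    out$data[ch, ] <- fir_apply(fir_apply(rec$data[ch, ], hp), lp)
  }
  out
}

#' Zero artifact segments
#'
#' Every 0.2 s sliding window (1-sample hop) in which the amplitude range
#' (max minus min) of ANY channel exceeds 80 microvolts is zeroed in ALL
#' channels; overlapping flagged windows are unioned.  The comparison is
#' strict (`>`), so an excursion of exactly the threshold is kept.  Zeroed
#' samples are recorded in the artifact mask.
#'
#' @param rec An [eeg_recording].
#' @param range_threshold Range threshold in microvolts.
#' @param window Window duration in seconds.
#' @return An [eeg_recording] with artifact segments zeroed and the mask set.
#' @export
artifact_zero <- function(rec, range_threshold = 80, window = 0.2) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (range_threshold <= 0 || window <= 0) {
    stop_invalid("threshold and window must be positive")
  }
  w <- as.integer(round(window * rec$rate))
  n <- ncol(rec$data)
  if (w < 2L) stop_invalid("window of %g s spans < 2 samples at %g Hz",
                           window, rec$rate)
  if (w > n) return(rec)
  flagged <- rep(FALSE, n - w + 1L)
  for (ch in seq_len(nrow(rec$data))) {
    flagged <- flagged | (.roll_range(rec$data[ch, ], w) > range_threshold)
  }
  if (!any(flagged)) return(rec)
  # Union of flagged windows via a coverage (difference) array.
  cover <- integer(n + 1L)
  starts <- which(flagged)
  tab_s <- tabulate(starts, nbins = n)
  tab_e <- tabulate(starts + w, nbins = n + 1L)
  mask <- cumsum(tab_s - tab_e[seq_len(n)]) > 0L
  out <- rec
  out$data[, mask] <- 0
  out$artifact_mask <- rec$artifact_mask | mask
  out
}

#' @rdname artifact_zero
#' @details `artifact_zero_reference()` is a brute-force reference
#'   implementation (naive O(n*w) window ranges, explicit window-by-window
#'   mask marking) kept for cross-checking the fast path; the two must agree
#'   bit-exactly on any input.
#' @export
artifact_zero_reference <- function(rec, range_threshold = 80, window = 0.2) {
  stopifnot(inherits(rec, "eeg_recording"))
  w <- as.integer(round(window * rec$rate))
  n <- ncol(rec$data)
  if (w > n) return(rec)
  flagged <- rep(FALSE, n - w + 1L)
  for (ch in seq_len(nrow(rec$data))) {
    flagged <- flagged | (.roll_range_naive(rec$data[ch, ], w) > range_threshold)
  }
  mask <- rep(FALSE, n)
  for (s in which(flagged)) mask[s:(s + w - 1L)] <- TRUE
  out <- rec
  out$data[, mask] <- 0
  out$artifact_mask <- rec$artifact_mask | mask
  out
}

#' Downsample to 512 Hz
#'
#' Keeps every second sample of a 1024 Hz recording.  The preceding 22 Hz
#' low-pass of [band_limit()] serves as the anti-aliasing filter.
#'
#' @param rec An [eeg_recording] at 1024 Hz.
#' @return An [eeg_recording] at 512 Hz.
#' @export
downsample_512 <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$rate != 1024) stop_invalid("downsampling is defined for 1024 Hz input")
  keep <- seq(1L, ncol(rec$data), by = 2L)
  eeg_recording(rec$data[, keep, drop = FALSE], 512, rec$labels,
                rec$reference, rec$artifact_mask[keep])
}

#' Final 10 Hz low-pass
#'
#' 251-tap Kaiser-window FIR low-pass at 10 Hz, applied at 512 Hz with
#' group-delay compensation; low-frequency EEG is the band most sensitive to
#' acoustic envelope features.
#'
#' @param rec An [eeg_recording] at 512 Hz.
#' @param lp_hz Cutoff (Hz).
#' @param taps Filter length.
#' @return The filtered [eeg_recording].
#' @export
lowpass_10hz <- function(rec, lp_hz = 10, taps = 251L) {
  stopifnot(inherits(rec, "eeg_recording"))
  lp <- fir_design(taps, lp_hz, rec$rate, "low", "kaiser")
  out <- rec
  for (ch in seq_len(nrow(rec$data))) {
    out$data[ch, ] <- fir_apply(rec$data[ch, ], lp)
  }
  out
}

#' @rdname downsample_512
#' @param smooth Also apply the 10 Hz low-pass after downsampling?
#' @export
downsample_and_smooth <- function(rec, smooth = TRUE) {
  out <- downsample_512(rec)
  if (smooth) out <- lowpass_10hz(out) else out
}

#' Run the full preprocessing chain
#'
#' Fixed-order conditioning: 60 Hz notch, linked-mastoid re-reference,
#' 0.7-22 Hz FIR band limiting, downsampling to 512 Hz, an optional
#' independent-component hook (identity by default; slot in an external ICA
#' cleanup here), artifact zeroing, and the final 10 Hz low-pass.
#'
#' @param rec A raw [eeg_recording] at 1024 Hz.
#' @param ica_hook Function `eeg_recording -> eeg_recording` applied after
#'   downsampling; defaults to the identity.
#' @param artifact_params List with `range_threshold` (microvolts) and
#'   `window` (s).
#' @return The analysis-ready [eeg_recording] at 512 Hz.
#' @export
preprocess_eeg <- function(rec, ica_hook = identity,
                           artifact_params = list(range_threshold = 80,
                                                  window = 0.2)) {
  rec |>
    notch_60hz() |>
    rereference_mastoids() |>
    band_limit() |>
    downsample_512() |>
    ica_hook() |>
    artifact_zero(range_threshold = artifact_params$range_threshold,
                  window = artifact_params$window) |>
    lowpass_10hz()
}
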