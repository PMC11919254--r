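#' Mono audio waveform
#'
#' Lightweight container for a single-channel audio signal.  All acoustic
#' processing in the package (mixing, masker synthesis, envelope extraction)
#' operates on `waveform` objects.
#'
#' @param samples Numeric vector of amplitudes (arbitrary units).
#' @param rate Sampling rate in Hz.
#' @return An object of class `waveform` with fields `samples` and `rate`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 1, by = 1 / 16000)), 16000)
#' rms(w)
#' @export
waveform <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop_invalid("waveform needs at least one sample")
  if (!all(is.finite(samples))) stop_invalid("waveform samples must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop_invalid("sampling rate must be a single positive number")
  }
  structure(list(samples = samples, rate = as.numeric(rate)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.2f s), rms %.4g\n",
              length(x$samples), x$rate, length(x$samples) / x$rate, rms(x)))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$samples)

duration <- function(w) length(w$samples) / w$rate

#' Read a mono WAV file
#'
#' Supports RIFF PCM (16- and 24-bit) and IEEE float (32-bit) encodings.
#' Multichannel files are rejected: the analysis chain is defined on mono
#' signals, and implicit downmixing would change RMS-based SNR levels.
#'
#' @param path Path to a `.wav` file.
#' @return A [waveform]. PCM samples are scaled to `[-1, 1)`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_invalid("not a RIFF file: %s", path)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop_invalid("not a WAVE file: %s", path)

  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) stop_invalid("no data chunk in %s", path)
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", size)
      fmt <- list(
        format    = sum(as.integer(raw_fmt[1:2]) * c(1, 256)),
        channels  = sum(as.integer(raw_fmt[3:4]) * c(1, 256)),
        rate      = sum(as.integer(raw_fmt[5:8]) * c(1, 256, 65536, 16777216)),
        bits      = sum(as.integer(raw_fmt[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop_invalid("data chunk before fmt chunk in %s", path)
      if (fmt$channels != 1L) {
        stop_invalid("only mono WAV supported, got %d channels", fmt$channels)
      }
      n <- size %/% (fmt$bits %/% 8L)
      samples <- if (fmt$format == 3L && fmt$bits == 32L) {
        readBin(con, "double", n, 4, endian = "little")
      } else if (fmt$format == 1L && fmt$bits == 16L) {
        readBin(con, "integer", n, 2, signed = TRUE, endian = "little") / 32768
      } else if (fmt$format == 1L && fmt$bits == 24L) {
        b <- readBin(con, "integer", 3L * n, 1, signed = FALSE, endian = "little")
        b <- matrix(b, nrow = 3L)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        ifelse(v >= 8388608, v - 16777216, v) / 8388608
      } else {
        stop_invalid("unsupported WAV encoding (format %d, %d bit)",
                     fmt$format, fmt$bits)
      }
      return(waveform(samples, fmt$rate))
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
  }
}

#' Write a mono WAV file
#'
#' @param wave A [waveform].
#' @param path Output path.
#' @param bits 32 (IEEE float, lossless round-trip) or 16 (PCM, quantized to
#'   `2^-15` resolution; samples must lie in `[-1, 1]`).
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, bits = 32L) {
  stopifnot(inherits(wave, "waveform"), bits %in% c(16L, 32L))
  n <- length(wave$samples)
  bytes_per <- bits %/% 8L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  fmt_code <- if (bits == 32L) 3L else 1L
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(wave$rate), con, 4, endian = "little")
  writeBin(as.integer(wave$rate * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 32L) {
    writeBin(wave$samples, con, 4, endian = "little")
  } else {
    if (max(abs(wave$samples)) > 1) {
      stop_invalid("16-bit PCM requires samples in [-1, 1]")
    }
    q <- as.integer(pmin(pmax(round(wave$samples * 32768), -32768), 32767))
    writeBin(q, con, 2, endian = "little")
  }
  invisible(path)
}
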