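#' Standard channel labels
#'
#' The 16 scalp electrodes (10-20 placement) plus left/right mastoids used
#' throughout the package, and the fronto-central cluster over which TRFs and
#' prediction accuracies are averaged (sensitive to auditory-cortex sources).
#'
#' @return Character vector of channel labels.
#' @export
eeg_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "C3", "Cz", "C4",
    "T7", "T8", "P3", "Pz", "P4", "Oz", "M1", "M2")
}

#' @rdname eeg_channels
#' @export
frontocentral_cluster <- function() c("F3", "Fz", "F4", "C3", "Cz", "C4")

#' Multichannel EEG recording
#'
#' @param data Channels x samples numeric matrix (microvolts).
#' @param rate Sampling rate in Hz.
#' @param labels Character vector of unique channel names, one per row.
#' @param reference `"raw"` or `"linked_mastoids"`.
#' @param artifact_mask Logical vector, one entry per sample; `TRUE` marks
#'   samples zeroed by artifact rejection.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, labels = eeg_channels(),
                          reference = c("raw", "linked_mastoids"),
                          artifact_mask = NULL) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop_invalid("EEG data must be finite")
  if (length(labels) != nrow(data)) {
    stop_invalid("got %d labels for %d channels", length(labels), nrow(data))
  }
  if (anyDuplicated(labels)) stop_invalid("channel labels must be unique")
  if (is.null(artifact_mask)) artifact_mask <- rep(FALSE, ncol(data))
  if (length(artifact_mask) != ncol(data)) {
    stop_invalid("artifact mask length must equal the number of samples")
  }
  rownames(data) <- labels
  structure(list(data = data, rate = as.numeric(rate),
                 labels = as.character(labels), reference = reference,
                 artifact_mask = as.logical(artifact_mask)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s), ref %s, %d samples masked\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate,
              x$reference, sum(x$artifact_mask)))
  invisible(x)
}

#' Convert an EEG recording to a long tibble
#'
#' @param x An [eeg_recording].
#' @param ... Unused.
#' @return A tibble with columns `time`, `channel`, `value`, `masked`.
#' @method tidy eeg_recording
#' @export
tidy.eeg_recording <- function(x, ...) {
  n <- ncol(x$data)
  tibble::tibble(
    time = rep((seq_len(n) - 1L) / x$rate, each = nrow(x$data)),
    channel = rep(x$labels, times = n),
    value = as.numeric(x$data),
    masked = rep(x$artifact_mask, each = nrow(x$data))
  )
}

#' Read and write EEG recordings as plain text
#'
#' The package container is a self-describing TSV: comment lines carry the
#' rate, reference state and artifact mask; the table holds one column per
#' channel.  Full double precision is preserved so round-trips are lossless.
#'
#' @param rec An [eeg_recording].
#' @param path File path.
#' @return `write_eeg()` returns `path` invisibly; `read_eeg()` an
#'   [eeg_recording].
#' @export
write_eeg <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# rate: %.17g", rec$rate),
    sprintf("# reference: %s", rec$reference),
    sprintf("# mask: %s", paste(as.integer(rec$artifact_mask), collapse = "")),
    paste(rec$labels, collapse = "\t")
  ), con)
  utils::write.table(
    matrix(sprintf("%.17g", t(rec$data)), ncol = nrow(rec$data)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname write_eeg
#' @export
read_eeg <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  get_field <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    if (length(ln) != 1L) stop_invalid("missing '%s' header in %s", key, path)
    trimws(sub(paste0("# ", key, ":"), "", ln, fixed = TRUE))
  }
  rate <- as.numeric(get_field("rate"))
  reference <- get_field("reference")
  mask <- as.integer(strsplit(get_field("mask"), "")[[1]]) == 1L
  body <- lines[!startsWith(lines, "# ")]
  labels <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  dat <- vapply(strsplit(body[-1], "\t", fixed = TRUE), as.numeric,
                numeric(length(labels)))
  dat <- matrix(dat, nrow = length(labels))
  if (ncol(dat) != length(mask)) {
    stop_invalid("mask length %d does not match %d samples in %s",
                 length(mask), ncol(dat), path)
  }
  eeg_recording(dat, rate, labels, reference, mask)
}
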