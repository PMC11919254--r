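#' Baseline-correct a TRF and average the fronto-central cluster
#'
#' Per channel, the mean weight over the baseline window (-0.15 to 0 s by
#' default) is subtracted at every lag; the baselined channels of the cluster
#' are then averaged into a single TRF time course, the unit entering all
#' component analyses.
#'
#' @param trf A `trf_model` whose lags cover the baseline window.
#' @param cluster Channel labels to average (all must be present).
#' @param baseline Baseline window in seconds, `c(min, max)`.
#' @return A tibble of class `trf_timecourse` with columns `lag`,
#'   `amplitude`.
#' @export
baseline_and_cluster <- function(trf, cluster = frontocentral_cluster(),
                                 baseline = c(-0.15, 0)) {
  stopifnot(inherits(trf, "trf_model"))
  # the lag grid must reach the baseline window to within one sample
  if (min(trf$lags) > baseline[1] + 1 / trf$rate ||
      max(trf$lags) < baseline[2] - 1 / trf$rate) {
    stop_invalid("TRF lags [%.3f, %.3f] do not cover the baseline window [%g, %g]",
                 min(trf$lags), max(trf$lags), baseline[1], baseline[2])
  }
  missing <- setdiff(cluster, rownames(trf$weights))
  if (length(missing) > 0L) {
    stop_invalid("cluster channel(s) missing from TRF: %s",
                 paste(missing, collapse = ", "))
  }
  in_base <- trf$lags >= baseline[1] - 1e-9 & trf$lags <= baseline[2] + 1e-9
  w <- trf$weights[cluster, , drop = FALSE]
  w <- w - rowMeans(w[, in_base, drop = FALSE])
  out <- tibble::tibble(lag = trf$lags, amplitude = colMeans(w))
  class(out) <- c("trf_timecourse", class(out))
  out
}

#' Default component search windows
#'
#' Lag windows for the P1 (early positive), N1 (negative) and P2 (late
#' positive) deflections of the auditory TRF, following canonical auditory
#' evoked-response morphology with the ordering constraint P1 < N1 < P2.
#'
#' @return Named list of `c(min, max)` windows in seconds.
#' @export
component_windows <- function() {
  list(P1 = c(0.02, 0.09), N1 = c(0.06, 0.16), P2 = c(0.14, 0.30))
}

#' Component latencies from a group-mean TRF time course
#'
#' P1 and P2 latencies are the lags of the maximum within their search
#' windows, N1 the lag of the minimum.  Latencies are estimated from the
#' across-participant mean time course, separately per condition; individual
#' participants contribute amplitudes only (see [component_amplitudes()]).
#' An extremum landing on a window edge raises a warning (possible
#' mis-specified window).
#'
#' @param timecourse A `trf_timecourse` (group mean).
#' @param windows Search windows, as from [component_windows()].
#' @return A tibble with columns `component`, `latency`.
#' @export
find_component_latencies <- function(timecourse, windows = component_windows()) {
  stopifnot(all(c("lag", "amplitude") %in% names(timecourse)))
  pick <- function(win, fun, name) {
    idx <- which(timecourse$lag >= win[1] - 1e-9 & timecourse$lag <= win[2] + 1e-9)
    if (length(idx) == 0L) stop_invalid("window [%g, %g] outside the lag range",
                                        win[1], win[2])
    k <- idx[fun(timecourse$amplitude[idx])]
    if (k == idx[1] || k == idx[length(idx)]) {
      warning(sprintf("%s extremum at edge of its search window [%g, %g] s",
                      name, win[1], win[2]))
    }
    timecourse$lag[k]
  }
  lat <- c(P1 = pick(windows$P1, which.max, "P1"),
           N1 = pick(windows$N1, which.min, "N1"),
           P2 = pick(windows$P2, which.max, "P2"))
  if (!(lat["P1"] < lat["N1"] && lat["N1"] < lat["P2"])) {
    warning("component latencies violate the P1 < N1 < P2 ordering")
  }
  tibble::tibble(component = names(lat), latency = unname(lat))
}

#' Component amplitudes and P1-N1 / P2-N1 differences
#'
#' Mean amplitude of an individual participant's TRF time course in a 0.02 s
#' window centered on each group-level peak latency, and the P1-minus-N1 and
#' P2-minus-N1 differences.  Differences rather than raw peaks are analyzed
#' because additive offsets of the TRF (such as the overall positive shift of
#' clear-speech TRFs) cancel in them.
#'
#' @param timecourse A participant's `trf_timecourse`.
#' @param latencies Tibble from [find_component_latencies()].
#' @param window Averaging window width in seconds (default 0.02).
#' @return A one-row tibble: `p1_latency`, `n1_latency`, `p2_latency`,
#'   `p1_amp`, `n1_amp`, `p2_amp`, `p1n1`, `p2n1`.
#' @export
component_amplitudes <- function(timecourse, latencies, window = 0.02) {
  stopifnot(all(c("component", "latency") %in% names(latencies)))
  lat <- stats::setNames(latencies$latency, latencies$component)
  half <- window / 2
  amp <- vapply(c("P1", "N1", "P2"), function(comp) {
    lo <- lat[comp] - half
    hi <- lat[comp] + half
    if (lo < min(timecourse$lag) - 1e-9 || hi > max(timecourse$lag) + 1e-9) {
      stop_invalid("%s amplitude window [%.3f, %.3f] outside the lag range",
                   comp, lo, hi)
    }
    idx <- timecourse$lag >= lo - 1e-9 & timecourse$lag <= hi + 1e-9
    mean(timecourse$amplitude[idx])
  }, numeric(1))
  tibble::tibble(
    p1_latency = unname(lat["P1"]), n1_latency = unname(lat["N1"]),
    p2_latency = unname(lat["P2"]),
    p1_amp = amp[["P1"]], n1_amp = amp[["N1"]], p2_amp = amp[["P2"]],
    p1n1 = amp[["P1"]] - amp[["N1"]],
    p2n1 = amp[["P2"]] - amp[["N1"]]
  )
}

#' Component table for a set of participants
#'
#' Applies the group-latency / individual-amplitude split: latencies are
#' estimated once from the across-participant mean time course, then each
#' participant's amplitudes are measured at those latencies.
#'
#' @param timecourses Named list of `trf_timecourse`s (one per participant),
#'   all on the same lag grid.
#' @param windows Component search windows.
#' @param window Amplitude averaging window (s).
#' @return A tibble with one row per participant plus the component columns
#'   of [component_amplitudes()].
#' @export
component_table <- function(timecourses, windows = component_windows(),
                            window = 0.02) {
  stopifnot(length(timecourses) >= 1L)
  lags <- timecourses[[1]]$lag
  amps <- vapply(timecourses, function(tc) tc$amplitude, numeric(length(lags)))
  group_mean <- tibble::tibble(lag = lags, amplitude = rowMeans(amps))
  lat <- find_component_latencies(group_mean, windows)
  ids <- names(timecourses)
  if (is.null(ids)) ids <- as.character(seq_along(timecourses))
  purrr::list_rbind(purrr::map2(timecourses, ids, function(tc, id) {
    dplyr::bind_cols(tibble::tibble(participant = id),
                     component_amplitudes(tc, lat, window))
  }))
}

#' Plot a TRF time course with component windows
#'
#' @param object A `trf_timecourse`.
#' @param latencies Optional tibble from [find_component_latencies()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trf_timecourse
#' @export
autoplot.trf_timecourse <- function(object, latencies = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$amplitude)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (s)", y = "TRF amplitude (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(latencies)) {
    p <- p + ggplot2::geom_vline(data = latencies,
                                 ggplot2::aes(xintercept = .data$latency),
                                 linetype = "dashed", color = "grey40")
  }
  p
}
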