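#' SNR condition profile
#'
#' Per-participant values of one metric (P1-N1, P2-N1, prediction accuracy,
#' or a behavioral score) across a descending grid of SNR conditions.
#'
#' @param x Condition SNRs in dB, strictly decreasing.
#' @param y Participants x conditions numeric matrix (columns align with
#'   `x`); a single profile may be given as a vector.
#' @param metric Label for the metric stored in the profile.
#' @return An object of class `snr_profile`.
#' @export
snr_profile <- function(x, y, metric = "metric") {
  if (is.vector(y)) y <- matrix(y, nrow = 1L)
  y <- as.matrix(y)
  if (ncol(y) != length(x)) {
    stop_invalid("y has %d columns for %d conditions", ncol(y), length(x))
  }
  if (any(diff(x) >= 0)) stop_invalid("condition SNRs must be strictly decreasing")
  if (anyNA(y)) stop_invalid("profile has missing cells")
  structure(list(x = as.numeric(x), y = y, metric = metric),
            class = "snr_profile")
}

#' @export
print.snr_profile <- function(x, ...) {
  cat(sprintf("<snr_profile:%s> %d participants x %d conditions (%+.1f..%+.1f dB)\n",
              x$metric, nrow(x$y), length(x$x), max(x$x), min(x$x)))
  invisible(x)
}

#' @method tidy snr_profile
#' @export
tidy.snr_profile <- function(x, ...) {
  tibble::tibble(
    participant = rep(seq_len(nrow(x$y)), times = length(x$x)),
    snr_db = rep(x$x, each = nrow(x$y)),
    value = as.numeric(x$y),
    metric = x$metric
  )
}

#' Sliding average over neighboring SNR conditions
#'
#' Averages each run of `window` consecutive SNR conditions, reducing noise
#' and matching the number of stories averaged for the clear condition
#' (three neighbors when three clear stories were presented, four when
#' four).  The output SNR of a window is its center level for odd windows
#' and the mean of its levels for even windows; on the 21-level grid from
#' +30 dB in 1.6 dB steps, a 3-neighbor average yields 19 conditions from
#' +28.4 down to -0.4 dB SNR.
#'
#' @param profile An [snr_profile].
#' @param window Number of neighbors to average (>= 1).
#' @return An [snr_profile] with `n - window + 1` conditions.
#' @export
sliding_average <- function(profile, window = 3L) {
  stopifnot(inherits(profile, "snr_profile"))
  window <- as.integer(window)
  n <- length(profile$x)
  if (window < 1L) stop_invalid("window must be >= 1")
  if (window > n) stop_invalid("window (%d) exceeds %d conditions", window, n)
  m <- n - window + 1L
  x_out <- vapply(seq_len(m), function(k) {
    win <- profile$x[k:(k + window - 1L)]
    if (window %% 2L == 1L) win[(window + 1L) %/% 2L] else mean(win)
  }, numeric(1))
  y_out <- vapply(seq_len(m), function(k) {
    rowMeans(profile$y[, k:(k + window - 1L), drop = FALSE])
  }, numeric(nrow(profile$y)))
  y_out <- matrix(y_out, nrow = nrow(profile$y))
  snr_profile(x_out, y_out, profile$metric)
}

paired_cohens_d <- function(diffs) mean(diffs) / stats::sd(diffs)

#' Paired comparisons of each SNR condition against clear speech
#'
#' Two-sided paired t-test of every condition column against the clear-speech
#' values, with Benjamini-Hochberg false-discovery-rate control over the
#' family of condition tests.  Cohen's d is the mean difference divided by
#' the SD of the differences.
#'
#' @param clear Per-participant values in the clear condition.
#' @param profile An [snr_profile] (same participants, same order).
#' @param q FDR level (default 0.05).
#' @param method FDR variant: Benjamini-Hochberg (`"BH"`, default) or
#'   Benjamini-Yekutieli (`"BY"`).
#' @return A tibble with columns `snr_db`, `t`, `dof`, `p`, `d`, `p_fdr`,
#'   `significant` (`p_fdr <= q`).
#' @export
paired_tests_vs_clear <- function(clear, profile, q = 0.05,
                                  method = c("BH", "BY")) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "snr_profile"))
  if (length(clear) != nrow(profile$y)) {
    stop_invalid("clear has %d participants, profile has %d",
                 length(clear), nrow(profile$y))
  }
  res <- purrr::map(seq_along(profile$x), function(k) {
    diffs <- profile$y[, k] - clear
    if (stats::sd(diffs) == 0) {
      stop_invalid("zero-variance differences at %+.1f dB: paired t undefined",
                   profile$x[k])
    }
    tt <- stats::t.test(profile$y[, k], clear, paired = TRUE)
    tibble::tibble(snr_db = profile$x[k], t = unname(tt$statistic),
                   dof = unname(tt$parameter), p = tt$p.value,
                   d = paired_cohens_d(diffs))
  })
  out <- purrr::list_rbind(res)
  out$p_fdr <- stats::p.adjust(out$p, method = method)
  out$significant <- out$p_fdr <= q
  out
}

#' One-sample t-test of per-participant slopes against zero
#'
#' @param slopes Per-participant slope estimates (length >= 2).
#' @return A one-row tibble: `t`, `dof`, `p`, `d` (mean/SD).  All-zero
#'   slopes give `t = 0, p = 1`; otherwise zero variance is an error.
#' @export
slope_ttest <- function(slopes) {
  if (length(slopes) < 2L) stop_invalid("need at least 2 participants")
  if (stats::sd(slopes) == 0) {
    if (all(slopes == 0)) {
      return(tibble::tibble(t = 0, dof = length(slopes) - 1L, p = 1, d = 0))
    }
    stop_invalid("zero-variance slopes with nonzero mean: t undefined")
  }
  tt <- stats::t.test(slopes, mu = 0)
  tibble::tibble(t = unname(tt$statistic), dof = unname(tt$parameter),
                 p = tt$p.value, d = mean(slopes) / stats::sd(slopes))
}

#' Broken-stick (piecewise) regression over SNR
#'
#' Grid search over the interior condition SNRs as candidate breakpoints.
#' At each candidate, two independent least-squares lines are fitted to the
#' across-participant average — one on the high-SNR side, one on the low-SNR
#' side, with the breakpoint condition included in BOTH pieces — and the
#' breakpoint minimizing the combined root-mean-squared error is selected
#' (ties broken toward the highest SNR).  Per-participant lines are then
#' fitted on each piece's SNR range and the slopes tested against zero with
#' a one-sample t-test per piece.
#'
#' @param profile An [snr_profile] with at least 5 conditions and 2
#'   participants.
#' @param shared_breakpoint Include the breakpoint condition in both pieces
#'   (default `TRUE`)?  `FALSE` assigns it to the high-SNR piece only.
#' @return An object of class `piecewise_fit`: `breakpoint` (dB),
#'   `slopes_group` (named, piece1 = high-SNR side), `slopes` (participants
#'   x 2 matrix), `tests` (tibble of per-piece slope t-tests), `rmse`,
#'   `candidates` (tibble `breakpoint`, `rmse`), `metric`.
#' @export
piecewise_fit <- function(profile, shared_breakpoint = TRUE) {
  stopifnot(inherits(profile, "snr_profile"))
  x <- profile$x
  n <- length(x)
  if (n < 5L) stop_invalid("need at least 5 conditions for a broken stick")
  if (nrow(profile$y) < 2L) stop_invalid("need at least 2 participants")
  ybar <- colMeans(profile$y)
  cand_idx <- 2L:(n - 1L)
  line_sse <- function(xx, yy) {
    fit <- stats::lm.fit(cbind(1, xx), yy)
    sum(fit$residuals^2)
  }
  rmse <- vapply(cand_idx, function(i) {
    i1 <- 1L:i
    i2 <- if (shared_breakpoint) i:n else (i + 1L):n
    if (length(i1) < 2L || length(i2) < 2L) return(NA_real_)
    sqrt((line_sse(x[i1], ybar[i1]) + line_sse(x[i2], ybar[i2])) /
           (length(i1) + length(i2)))
  }, numeric(1))
  if (all(is.na(rmse))) stop_invalid("no valid breakpoint candidate")
  # ties (to within numerical noise) break toward the highest SNR
  tol <- 1e-8 * (diff(range(ybar)) + 1e-12)
  best <- cand_idx[which(rmse <= min(rmse, na.rm = TRUE) + tol)[1]]
  i1 <- 1L:best
  i2 <- if (shared_breakpoint) best:n else (best + 1L):n
  slope_of <- function(xx, yy) unname(stats::lm.fit(cbind(1, xx), yy)$coefficients[2])
  slopes_group <- c(piece1 = slope_of(x[i1], ybar[i1]),
                    piece2 = slope_of(x[i2], ybar[i2]))
  slopes <- t(apply(profile$y, 1, function(row) {
    c(slope_of(x[i1], row[i1]), slope_of(x[i2], row[i2]))
  }))
  colnames(slopes) <- c("piece1", "piece2")
  tests <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(piece = "piece1"), slope_ttest(slopes[, 1])),
    dplyr::bind_cols(tibble::tibble(piece = "piece2"), slope_ttest(slopes[, 2]))
  )
  structure(list(
    breakpoint = x[best],
    slopes_group = slopes_group,
    slopes = slopes,
    tests = tests,
    rmse = min(rmse, na.rm = TRUE),
    candidates = tibble::tibble(breakpoint = x[cand_idx], rmse = rmse),
    metric = profile$metric,
    x = x, ybar = ybar, pieces = list(i1 = i1, i2 = i2)
  ), class = "piecewise_fit")
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf("<piecewise_fit:%s> breakpoint %+.1f dB SNR, slopes %.4g / %.4g, rmse %.4g\n",
              x$metric, x$breakpoint, x$slopes_group[1], x$slopes_group[2],
              x$rmse))
  invisible(x)
}

#' Tidy and summarize a broken-stick fit
#'
#' @param x A `piecewise_fit`.
#' @param ... Unused.
#' @return `tidy()`: per-piece tibble with group slope and the slope t-test;
#'   `glance()`: one-row tibble with `breakpoint`, `rmse`, `n_participants`.
#' @method tidy piecewise_fit
#' @export
tidy.piecewise_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(slope = unname(x$slopes_group)),
    x$tests
  )[, c("piece", "slope", "t", "dof", "p", "d")]
}

#' @rdname tidy.piecewise_fit
#' @method glance piecewise_fit
#' @export
glance.piecewise_fit <- function(x, ...) {
  tibble::tibble(breakpoint = x$breakpoint, rmse = x$rmse,
                 n_participants = nrow(x$slopes), metric = x$metric)
}

#' Plot a broken-stick fit over the group-mean profile
#'
#' @param object A `piecewise_fit`.
#' @param ... Unused.
#' @return A ggplot object (SNR decreasing left to right, as profiles are
#'   read from easy to hard listening conditions).
#' @method autoplot piecewise_fit
#' @export
autoplot.piecewise_fit <- function(object, ...) {
  pts <- tibble::tibble(snr_db = object$x, value = object$ybar)
  seg <- purrr::map(object$pieces, function(idx) {
    fit <- stats::lm.fit(cbind(1, object$x[idx]), object$ybar[idx])
    tibble::tibble(snr_db = range(object$x[idx]),
                   value = fit$coefficients[1] + fit$coefficients[2] *
                     range(object$x[idx]))
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$snr_db, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = seg$i1, color = "firebrick") +
    ggplot2::geom_line(data = seg$i2, color = "steelblue") +
    ggplot2::geom_vline(xintercept = object$breakpoint, linetype = "dashed") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "SNR (dB)", y = object$metric,
                  title = sprintf("Breakpoint %+.1f dB SNR", object$breakpoint)) +
    ggplot2::theme_minimal()
}
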