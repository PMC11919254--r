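#' Lagged design matrix for TRF estimation
#'
#' One column per lag on the uniform grid `lag_min, lag_min + 1/rate, ...,
#' lag_max`; column `j` at row `t` holds `env(t - lag_j)`.  Samples falling
#' outside the envelope are zero-padded (the story edge convention).
#'
#' @param env An [envelope_series].
#' @param lag_min,lag_max Lag range in seconds (`lag_min < lag_max`).
#' @return Numeric matrix, `length(env)` rows and
#'   `round((lag_max - lag_min) * rate) + 1` columns; lag grid in attribute
#'   `"lags"`.
#' @export
build_design_matrix <- function(env, lag_min, lag_max) {
  stopifnot(inherits(env, "envelope_series"))
  if (!(lag_min < lag_max)) stop_invalid("need lag_min < lag_max")
  rate <- env$rate
  n <- length(env$values)
  # lag grid: every integer sample shift whose lag lies inside [lag_min,
  # lag_max]; 0-0.4 s at 512 Hz gives 205 columns
  shift0 <- as.integer(ceiling(lag_min * rate - 1e-9))
  shift1 <- as.integer(floor(lag_max * rate + 1e-9))
  n_lags <- shift1 - shift0 + 1L
  if (n <= n_lags) {
    stop_invalid("envelope too short (%d samples) for %d lags", n, n_lags)
  }
  lags <- (shift0 + seq_len(n_lags) - 1L) / rate
  X <- matrix(0, n, n_lags)
  v <- env$values
  for (j in seq_len(n_lags)) {
    s <- shift0 + j - 1L            # env index offset: column = env(t - s)
    if (s >= 0L) {
      if (s < n) X[(s + 1L):n, j] <- v[seq_len(n - s)]
    } else {
      if (-s < n) X[seq_len(n + s), j] <- v[(1L - s):n]
    }
  }
  attr(X, "lags") <- lags
  X
}

#' Ridge-regularized TRF model
#'
#' Forward (encoding) model mapping the stimulus envelope onto each EEG
#' channel: per channel, weights solve `(Xz' Xz / (n-1) + lambda I) w =
#' Xz' y / (n-1)` where `Xz` is the lagged design matrix with z-scored
#' columns and `y` the mean-centered channel.  Normalizing the scatter
#' matrix to a correlation matrix (unit diagonal) makes the fixed
#' `lambda = 10` a data-size-independent smoother.  Weights are returned on
#' the original envelope scale (divided by the column SDs) so that noiseless
#' simulations are recovered exactly at `lambda = 0`; the convention is
#' recorded in the model so fits are comparable.
#'
#' @param env An [envelope_series] aligned with the EEG.
#' @param eeg An [eeg_recording] at the same rate and length.
#' @param lambda Ridge parameter on the z-scored scale (default 10).
#' @param lags Lag range in seconds, `c(min, max)`; `c(0, 0.4)` for
#'   prediction, `c(-0.15, 0.5)` for component analysis.
#' @return An object of class `trf_model`: `weights` (channels x lags),
#'   `lags`, `lambda`, `rate`, `channels`, `normalization`.
#' @export
fit_trf_ridge <- function(env, eeg, lambda = 10, lags = c(0, 0.4)) {
  stopifnot(inherits(env, "envelope_series"), inherits(eeg, "eeg_recording"))
  if (env$rate != eeg$rate) stop_invalid("envelope and EEG rates differ")
  if (length(env$values) != ncol(eeg$data)) {
    stop_invalid("envelope and EEG lengths differ (%d vs %d)",
                 length(env$values), ncol(eeg$data))
  }
  X <- build_design_matrix(env, lags[1], lags[2])
  lag_grid <- attr(X, "lags")
  stats <- design_stats(X, t(eeg$data))
  sol <- ridge_from_stats(stats, lambda)
  new_trf_model(sol, lag_grid, lambda, eeg$rate, eeg$labels)
}

# Sufficient statistics of a (sub)design: raw cross-products plus column
# sums, enough to reconstruct the centered, z-scored normal equations.
design_stats <- function(X, Y) {
  list(XtX = crossprod(X), XtY = crossprod(X, Y),
       xs = colSums(X), ys = colSums(Y), n = nrow(X))
}

add_stats <- function(a, b) {
  list(XtX = a$XtX + b$XtX, XtY = a$XtY + b$XtY,
       xs = a$xs + b$xs, ys = a$ys + b$ys, n = a$n + b$n)
}

# Solve the ridge normal equations on z-scored columns from accumulated
# sufficient statistics; returns weights mapped back to the raw envelope
# scale.  Algebraically identical to z-scoring the concatenated design.
# The scatter matrix is normalized by (n - 1) so that its diagonal is 1 (a
# correlation matrix): lambda is then commensurate with the unit predictor
# variance, which is what makes a fixed lambda = 10 a meaningful smoother
# regardless of story length.
ridge_from_stats <- function(st, lambda) {
  n <- st$n
  mu <- st$xs / n
  v <- (diag(st$XtX) - n * mu^2) / (n - 1)
  sdv <- sqrt(pmax(v, 0))
  sdv[sdv == 0] <- 1                      # constant columns get zero weight
  Sc <- st$XtX - n * tcrossprod(mu)
  Bc <- st$XtY - outer(mu, st$ys)
  Sz <- Sc / tcrossprod(sdv) / (n - 1)
  Bz <- (Bc / sdv) / (n - 1)
  L <- length(mu)
  wz <- tryCatch(
    solve(Sz + diag(lambda, L), Bz),
    error = function(e) {
      stop_invalid(paste0("normal equations are singular; use lambda > 0 ",
                          "to regularize (", conditionMessage(e), ")"))
    }
  )
  list(weights = t(wz / sdv), col_mean = mu, col_sd = sdv,
       y_mean = st$ys / n)
}

new_trf_model <- function(sol, lags, lambda, rate, channels) {
  w <- sol$weights
  rownames(w) <- channels
  structure(list(
    weights = w, lags = lags, lambda = lambda, rate = rate,
    channels = channels,
    normalization = list(predictor = "z-scored design columns",
                         response = "mean-centered (original units)",
                         col_mean = sol$col_mean, col_sd = sol$col_sd,
                         y_mean = sol$y_mean)
  ), class = "trf_model")
}

#' @export
print.trf_model <- function(x, ...) {
  cat(sprintf("<trf_model> %d channels, lags %.3f..%.3f s (%d), lambda = %g\n",
              nrow(x$weights), min(x$lags), max(x$lags), length(x$lags),
              x$lambda))
  invisible(x)
}

#' Tidy a TRF model into a long tibble
#'
#' @param x A `trf_model`.
#' @param ... Unused.
#' @return A tibble with columns `channel`, `lag`, `weight`.
#' @method tidy trf_model
#' @export
tidy.trf_model <- function(x, ...) {
  tibble::tibble(
    channel = rep(rownames(x$weights), times = length(x$lags)),
    lag = rep(x$lags, each = nrow(x$weights)),
    weight = as.numeric(x$weights)
  )
}

#' @rdname tidy.trf_model
#' @return `glance()`: a one-row tibble with `lambda`, `n_channels`,
#'   `n_lags`, `lag_min`, `lag_max`, `rate`.
#' @method glance trf_model
#' @export
glance.trf_model <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, n_channels = nrow(x$weights),
                 n_lags = length(x$lags), lag_min = min(x$lags),
                 lag_max = max(x$lags), rate = x$rate)
}

#' Predict EEG from a TRF model
#'
#' @param object A `trf_model`.
#' @param env An [envelope_series] at the model's rate.
#' @param ... Unused.
#' @return Samples x channels matrix of predicted EEG.
#' @export
predict.trf_model <- function(object, env, ...) {
  X <- build_design_matrix(env, min(object$lags), max(object$lags))
  pred <- X %*% t(object$weights)
  colnames(pred) <- rownames(object$weights)
  pred
}

#' EEG prediction accuracy of a TRF model
#'
#' Pearson correlation between the TRF-predicted and observed EEG, per
#' channel, summarized as the mean over a channel subset (by default the
#' fronto-central cluster when present, otherwise all channels).  Constant
#' predictions or constant EEG give `NA` with a warning.
#'
#' @param trf A `trf_model`.
#' @param env An [envelope_series].
#' @param eeg The observed [eeg_recording].
#' @param channels Channels entering the summary mean.
#' @return A list of class `prediction_accuracy`: `r_per_channel` (tibble
#'   `channel`, `r`) and `r_mean`.
#' @export
predict_accuracy <- function(trf, env, eeg, channels = NULL) {
  pred <- predict(trf, env)
  r <- vapply(seq_along(eeg$labels), function(ch) {
    safe_cor(pred[, ch], eeg$data[ch, ])
  }, numeric(1))
  tab <- tibble::tibble(channel = eeg$labels, r = r)
  if (is.null(channels)) {
    channels <- intersect(frontocentral_cluster(), eeg$labels)
    if (length(channels) == 0L) channels <- eeg$labels
  }
  structure(list(
    r_per_channel = tab,
    r_mean = mean(tab$r[tab$channel %in% channels])
  ), class = "prediction_accuracy")
}

safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("correlation undefined for constant input; returning NA")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Snippet scheme for cross-validated TRF estimation
#'
#' @param n_snippets Number of snippets (default 50).
#' @param duration Snippet duration in seconds (default 25).
#' @param seed Seed for the random snippet starts (mandatory).
#' @return A list of class `snippet_scheme`.
#' @export
snippet_scheme <- function(n_snippets = 50L, duration = 25, seed) {
  if (missing(seed)) stop_invalid("snippet_scheme requires an explicit seed")
  if (n_snippets < 2L) stop_invalid("need at least 2 snippets")
  structure(list(n_snippets = as.integer(n_snippets), duration = duration,
                 seed = as.integer(seed)),
            class = "snippet_scheme")
}

#' Snippet-based cross-validated TRF and prediction accuracy
#'
#' Draws `n_snippets` random snippet start times (uniform on the sample grid,
#' without replacement).  Each snippet is held out once; the training set is
#' every snippet that does not overlap the held-out one (training snippets
#' may overlap each other, increasing the usable data in short stories).
#' Training cross-products are accumulated across snippets — algebraically
#' identical to concatenating them — and the TRF is averaged across the
#' folds.  Accuracy is the Pearson correlation between predicted and observed
#' EEG on each held-out snippet, averaged over folds and channels.
#'
#' @inheritParams fit_trf_ridge
#' @param scheme A [snippet_scheme].
#' @param channels Channels entering the accuracy summary (default: the
#'   fronto-central cluster when present).
#' @return A list of class `trf_crossval`: `trf` (fold-averaged
#'   `trf_model`), `accuracy` (tibble `fold`, `channel`, `r`), `r_mean`,
#'   `starts` (snippet start samples).
#' @export
snippet_crossval <- function(env, eeg, scheme, lambda = 10, lags = c(0, 0.4),
                             channels = NULL) {
  stopifnot(inherits(env, "envelope_series"), inherits(eeg, "eeg_recording"),
            inherits(scheme, "snippet_scheme"))
  if (env$rate != eeg$rate) stop_invalid("envelope and EEG rates differ")
  n <- length(env$values)
  len <- as.integer(round(scheme$duration * env$rate))
  if (n < len) {
    stop_invalid("story (%.1f s) shorter than the %g s snippet duration",
                 n / env$rate, scheme$duration)
  }
  n_starts <- n - len + 1L
  if (n_starts < scheme$n_snippets) {
    stop_invalid("story too short for %d distinct snippet starts",
                 scheme$n_snippets)
  }
  starts <- with_seed(scheme$seed,
                      sort(sample.int(n_starts, scheme$n_snippets)))
  X <- build_design_matrix(env, lags[1], lags[2])
  lag_grid <- attr(X, "lags")
  Y <- t(eeg$data)
  snip_stats <- lapply(starts, function(s) {
    idx <- s:(s + len - 1L)
    design_stats(X[idx, , drop = FALSE], Y[idx, , drop = FALSE])
  })
  if (is.null(channels)) {
    channels <- intersect(frontocentral_cluster(), eeg$labels)
    if (length(channels) == 0L) channels <- eeg$labels
  }
  ch_idx <- match(channels, eeg$labels)

  folds <- vector("list", scheme$n_snippets)
  w_sum <- NULL
  n_fits <- 0L
  for (i in seq_along(starts)) {
    train <- which(abs(starts - starts[i]) >= len)
    if (length(train) == 0L) {
      warning(sprintf("fold %d has no non-overlapping training snippets; skipped", i))
      next
    }
    st <- Reduce(add_stats, snip_stats[train])
    sol <- ridge_from_stats(st, lambda)
    idx <- starts[i]:(starts[i] + len - 1L)
    pred <- X[idx, , drop = FALSE] %*% t(sol$weights)
    r <- vapply(ch_idx, function(ch) safe_cor(pred[, ch], Y[idx, ch]),
                numeric(1))
    folds[[i]] <- tibble::tibble(fold = i, channel = channels, r = r)
    w_sum <- if (is.null(w_sum)) sol$weights else w_sum + sol$weights
    n_fits <- n_fits + 1L
  }
  if (n_fits == 0L) stop_invalid("no fold had usable training data")
  acc <- dplyr::bind_rows(folds)
  mean_sol <- list(weights = w_sum / n_fits, col_mean = NULL, col_sd = NULL,
                   y_mean = NULL)
  structure(list(
    trf = new_trf_model(mean_sol, lag_grid, lambda, eeg$rate, eeg$labels),
    accuracy = acc,
    r_mean = mean(acc$r, na.rm = TRUE),
    starts = starts
  ), class = "trf_crossval")
}

#' @export
print.trf_crossval <- function(x, ...) {
  cat(sprintf("<trf_crossval> %d folds, mean prediction r = %.4f\n",
              length(unique(x$accuracy$fold)), x$r_mean))
  invisible(x)
}

#' Cross-correlation tracking measure
#'
#' Normalized cross-correlation (Pearson correlation at each lag) between the
#' envelope and each EEG channel over an analysis lag range; a model-free
#' alternative to the TRF that gives very similar tracking time courses.
#' At each lag the correlation is computed over the overlapping samples.
#'
#' @inheritParams fit_trf_ridge
#' @param lags Lag range in seconds (EEG lagging the envelope is positive).
#' @return A tibble with columns `lag`, `channel`, `r`.
#' @export
crosscorr_tracking <- function(env, eeg, lags = c(-0.15, 0.5)) {
  stopifnot(inherits(env, "envelope_series"), inherits(eeg, "eeg_recording"))
  if (env$rate != eeg$rate) stop_invalid("envelope and EEG rates differ")
  n <- length(env$values)
  if (n != ncol(eeg$data)) stop_invalid("envelope and EEG lengths differ")
  rate <- env$rate
  shifts <- as.integer(round(lags[1] * rate)):as.integer(round(lags[2] * rate))
  out <- lapply(shifts, function(s) {
    # EEG at time t compared against env at time t - s
    if (s >= 0L) {
      e_idx <- seq_len(n - s); g_idx <- (s + 1L):n
    } else {
      e_idx <- (1L - s):n; g_idx <- seq_len(n + s)
    }
    r <- vapply(seq_along(eeg$labels), function(ch) {
      safe_cor(env$values[e_idx], eeg$data[ch, g_idx])
    }, numeric(1))
    tibble::tibble(lag = s / rate, channel = eeg$labels, r = r)
  })
  dplyr::bind_rows(out)
}

#' Plot a TRF model
#'
#' @param object A `trf_model`.
#' @param channels Channels to draw (default: fronto-central cluster).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trf_model
#' @export
autoplot.trf_model <- function(object, channels = NULL, ...) {
  td <- tidy(object)
  if (is.null(channels)) {
    channels <- intersect(frontocentral_cluster(), unique(td$channel))
    if (length(channels) == 0L) channels <- unique(td$channel)
  }
  td <- dplyr::filter(td, .data$channel %in% channels)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$lag, y = .data$weight,
                                   color = .data$channel)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (s)", y = "TRF weight (a.u.)",
                  title = sprintf("TRF (lambda = %g)", object$lambda)) +
    ggplot2::theme_minimal()
}
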