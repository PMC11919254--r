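test_that("lagged design matrix matches the shift-and-stack oracle", {
  env <- rand_env(400, seed = 30)
  X <- build_design_matrix(env, 0, 0.02)
  expect_equal(ncol(X), floor(0.02 * 512) + 1)
  expect_equal(unname(X), design_oracle(env$values, 512, 0, 0.02),
               ignore_attr = TRUE)
  # negative lags too
  Xn <- build_design_matrix(env, -0.01, 0.03)
  expect_equal(unname(Xn), design_oracle(env$values, 512, -0.01, 0.03),
               ignore_attr = TRUE)
  # prediction lag range at 512 Hz has 205 columns
  env_long <- rand_env(2000, seed = 31)
  expect_equal(ncol(build_design_matrix(env_long, 0, 0.4)), 205)
  # unit impulse propagates along the anti-diagonal
  imp <- envelope_series(c(numeric(99), 1, numeric(200)), 512, "onset")
  Xi <- build_design_matrix(imp, 0, 0.01)
  expect_equal(ncol(Xi), 6)
  for (j in 1:6) expect_equal(which(Xi[, j] == 1), 99 + j)
  expect_error(build_design_matrix(rand_env(100), 0, 0.4), "too short")
})

test_that("ridge fit equals the explicit normal-equation oracle", {
  for (i in 1:20) {
    n <- sample(30:100, 1)
    env <- rand_env(n, seed = 300 + i)
    eeg <- rand_eeg(n, seed = 400 + i)
    lam <- sample(c(0.1, 1, 10), 1)
    trf <- fit_trf_ridge(env, eeg, lambda = lam, lags = c(0, 0.02))
    X <- build_design_matrix(env, 0, 0.02)
    W <- ridge_oracle(X, t(eeg$data), lam)
    expect_lt(max(abs(trf$weights - W)), 1e-10)
  }
})

test_that("noiseless data are recovered exactly at lambda = 0 and shrink as lambda grows", {
  set.seed(32)
  env <- rand_env(3000, seed = 33)
  X <- build_design_matrix(env, 0, 0.02)
  w_true <- rnorm(ncol(X))
  y <- X %*% w_true
  eeg <- eeg_recording(t(y), 512, "Cz", "linked_mastoids")
  trf0 <- fit_trf_ridge(env, eeg, lambda = 0, lags = c(0, 0.02))
  expect_equal(as.numeric(trf0$weights), w_true, tolerance = 1e-6)
  trf_big <- fit_trf_ridge(env, eeg, lambda = 1e9, lags = c(0, 0.02))
  expect_lt(max(abs(trf_big$weights)), 1e-6 * max(abs(trf0$weights)))
  # rank-deficient design at lambda = 0 errors with advice
  env_const <- envelope_series(rep(c(1, 1), 500), 512, "onset")
  eeg2 <- rand_eeg(1000, seed = 34)
  expect_error(fit_trf_ridge(env_const, eeg2, lambda = 0, lags = c(0, 0.02)),
               "lambda > 0")
})

test_that("snippet cross-validation is seeded, accurate on noiseless data, and null on noise", {
  env <- gen_speechlike_envelope(90, seed = 35)
  eeg <- gen_linear_eeg(env, response_snr_db = Inf, seed = 36)
  sch <- snippet_scheme(12, 25, seed = 37)
  cv1 <- snippet_crossval(env, eeg, sch, lambda = 10)
  cv2 <- snippet_crossval(env, eeg, sch, lambda = 10)
  expect_identical(cv1$starts, cv2$starts)
  expect_identical(cv1$trf$weights, cv2$trf$weights)
  expect_identical(cv1$r_mean, cv2$r_mean)
  expect_gte(cv1$r_mean, 0.99)
  # EEG independent of the envelope: fold correlations are null-small
  set.seed(38)
  noise_eeg <- eeg_recording(matrix(rnorm(ncol(eeg$data) * 2), 2),
                             512, c("Cz", "Fz"), "linked_mastoids")
  cvn <- snippet_crossval(env, noise_eeg, sch, lambda = 10,
                          channels = c("Cz", "Fz"))
  expect_lt(abs(mean(cvn$accuracy$r)), 2 / sqrt(25 * 512))
  expect_error(
    snippet_crossval(rand_env(20 * 512, seed = 1),
                     rand_eeg(20 * 512, seed = 2),
                     snippet_scheme(50, 25, seed = 3)),
    "shorter than")
})

test_that("fold-averaged TRF converges to the full-data fit on noiseless data", {
  env <- gen_speechlike_envelope(90, seed = 40)
  eeg <- gen_linear_eeg(env, response_snr_db = Inf, seed = 41)
  cv <- snippet_crossval(env, eeg, snippet_scheme(30, 25, seed = 42),
                         lambda = 10)
  full <- fit_trf_ridge(env, eeg, lambda = 10, lags = c(0, 0.4))
  expect_gt(cor(as.numeric(cv$trf$weights), as.numeric(full$weights)), 0.99)
})

test_that("prediction accuracy behaves like a Pearson correlation", {
  env <- rand_env(5000, seed = 43)
  trf <- fit_trf_ridge(env, rand_eeg(5000, seed = 44), 1, c(0, 0.02))
  pred <- predict(trf, env)
  self <- eeg_recording(t(pred), 512, c("Cz", "Fz"), "linked_mastoids")
  acc <- predict_accuracy(trf, env, self, channels = c("Cz", "Fz"))
  expect_equal(acc$r_mean, 1, tolerance = 1e-12)
  anti <- eeg_recording(-t(pred), 512, c("Cz", "Fz"), "linked_mastoids")
  expect_equal(predict_accuracy(trf, env, anti, c("Cz", "Fz"))$r_mean, -1,
               tolerance = 1e-12)
  # affine rescaling of the EEG leaves accuracy unchanged
  aff <- eeg_recording(3 * t(pred) + 7, 512, c("Cz", "Fz"), "linked_mastoids")
  expect_equal(predict_accuracy(trf, env, aff, c("Cz", "Fz"))$r_mean, 1,
               tolerance = 1e-12)
  # unrelated signals give near-zero correlations
  for (s in 1:10) {
    other <- rand_eeg(5000, seed = 500 + s)
    expect_lt(abs(predict_accuracy(trf, env, other, c("Cz", "Fz"))$r_mean), 0.05)
  }
  const <- eeg_recording(matrix(1, 2, 5000), 512, c("Cz", "Fz"),
                         "linked_mastoids")
  expect_warning(acc0 <- predict_accuracy(trf, env, const), "constant")
  expect_true(is.na(acc0$r_mean))
})

test_that("cross-correlation tracking equals a per-lag Pearson oracle and finds shifts", {
  env <- rand_env(4000, seed = 45)
  shift <- round(0.1 * 512)
  shifted <- c(numeric(shift), env$values[1:(4000 - shift)])
  eeg <- eeg_recording(rbind(shifted, env$values), 512, c("Cz", "Fz"),
                       "linked_mastoids")
  cc <- crosscorr_tracking(env, eeg, lags = c(-0.15, 0.5))
  cz <- dplyr::filter(cc, channel == "Cz")
  expect_equal(cz$lag[which.max(cz$r)], shift / 512, tolerance = 1 / 512 + 1e-12)
  fz <- dplyr::filter(cc, channel == "Fz")
  expect_equal(fz$r[fz$lag == 0], 1, tolerance = 1e-12)
  # oracle: direct Pearson at each lag over the overlap
  n <- 4000
  for (lag_s in c(-0.05, 0, 0.12)) {
    s <- round(lag_s * 512)
    idx_e <- if (s >= 0) 1:(n - s) else (1 - s):n
    idx_g <- if (s >= 0) (s + 1):n else 1:(n + s)
    expect_equal(cz$r[abs(cz$lag - s / 512) < 1e-9],
                 cor(env$values[idx_e], shifted[idx_g]), tolerance = 1e-10)
  }
})

test_that("TRF tidiers and plots expose the model", {
  env <- rand_env(1000, seed = 46)
  eeg <- rand_eeg(1000, seed = 47, labels = frontocentral_cluster())
  trf <- fit_trf_ridge(env, eeg, 10, c(0, 0.05))
  td <- tidy(trf)
  expect_identical(names(td), c("channel", "lag", "weight"))
  expect_equal(nrow(td), 6 * length(trf$lags))
  gl <- glance(trf)
  expect_equal(gl$lambda, 10)
  expect_equal(gl$n_lags, length(trf$lags))
  expect_s3_class(autoplot(trf), "ggplot")
})
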