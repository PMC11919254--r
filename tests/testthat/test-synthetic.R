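test_that("speech-like envelopes have Poisson event statistics and are reproducible", {
  env <- gen_speechlike_envelope(30, seed = 70)
  expect_true(all(env$values >= 0))
  expect_identical(gen_speechlike_envelope(30, seed = 70)$values, env$values)
  expect_false(identical(gen_speechlike_envelope(30, seed = 71)$values,
                         env$values))
  expect_error(gen_speechlike_envelope(10, seed = 1), "25 s")
  expect_error(gen_speechlike_envelope(30, syllable_rate = 0.5, seed = 1),
               "syllable_rate")
  # event counts stay within 3 sd of the Poisson expectation
  expected <- 30 * 4
  hits <- 0
  for (s in 1:20) {
    e <- gen_speechlike_envelope(30, seed = 700 + s)
    if (abs(attr(e, "n_events") - expected) <= 3 * sqrt(expected)) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("linear-mode EEG supports noiseless recovery and scales linearly", {
  env <- gen_speechlike_envelope(90, seed = 72)
  eeg <- gen_linear_eeg(env, response_snr_db = Inf, seed = 73)
  cv <- snippet_crossval(env, eeg, snippet_scheme(8, 25, seed = 74), 10)
  expect_gte(cv$r_mean, 0.99)
  # zero kernel leaves pure 1/f noise with null prediction accuracy
  k0 <- kernel_spec(tibble::tibble(latency = 0.1, amplitude = 0, width = 0.02))
  eeg0 <- gen_linear_eeg(env, kernel = k0, response_snr_db = -10, seed = 75)
  trf <- fit_trf_ridge(env, eeg0, 10, c(0, 0.4))
  acc <- predict_accuracy(trf, env, eeg0)
  expect_lt(abs(acc$r_mean), 0.15)
  # doubling the kernel amplitude doubles the estimated TRF
  k1 <- kernel_spec()
  k2 <- kernel_spec(dplyr::mutate(kernel_spec()$deflections,
                                  amplitude = amplitude * 2))
  e1 <- gen_linear_eeg(env, k1, response_snr_db = 20, seed = 76)
  e2 <- gen_linear_eeg(env, k2, response_snr_db = 20, seed = 76)
  t1 <- fit_trf_ridge(env, e1, 10, c(0, 0.4))
  t2 <- fit_trf_ridge(env, e2, 10, c(0, 0.4))
  ratio <- max(abs(t2$weights["Cz", ])) / max(abs(t1$weights["Cz", ]))
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("the threshold population is silent when subthreshold and linear when suprathreshold", {
  env <- gen_speechlike_envelope(30, seed = 77)
  envn <- envelope_series(env$values / max(env$values), 512, "onset")
  # subthreshold, no noise, no masker: nothing comes out
  p_sub <- sr_encoder_params(gain = 0.6, threshold = 1, internal_noise_sd = 0)
  expect_true(all(sr_population_response(envn, NULL, p_sub, seed = 1) == 0))
  # fully suprathreshold, no noise: output is the shifted drive, tracking r ~ 1
  p_sup <- sr_encoder_params(gain = 2, threshold = -0.5, internal_noise_sd = 0)
  pop <- sr_population_response(envn, NULL, p_sup, seed = 1)
  expect_equal(pop, 2 * envn$values + 0.5, tolerance = 1e-12)
  expect_equal(cor(pop, envn$values), 1, tolerance = 1e-12)
  # seeded determinism with internal noise
  p_n <- sr_encoder_params(gain = 0.6, threshold = 1, internal_noise_sd = 0.05)
  expect_identical(sr_population_response(envn, NULL, p_n, seed = 5),
                   sr_population_response(envn, NULL, p_n, seed = 5))
})

test_that("a masker sweep shows the stochastic-resonance inverted U", {
  env <- gen_speechlike_envelope(40, seed = 78)
  envn <- envelope_series(env$values / max(env$values), 512, "onset")
  masker <- gen_masker_envelope(40, seed = 79)
  expect_equal(max(masker$values), 1)
  gains <- c(0, 0.25, 0.5, 1, 1.5, 2, 3, 4.5, 7, 10)
  sub <- sr_masker_sweep(envn, masker,gains,
                         sr_encoder_params(gain = 0.6, threshold = 1,
                                           internal_noise_sd = 0.05),
                         seed = 80)
  am <- which.max(sub$locked_r2)
  expect_gt(am, 1)
  expect_lt(am, length(gains))
  expect_gt(max(sub$locked_r2), sub$locked_r2[1])
  sup <- sr_masker_sweep(envn, masker, gains,
                         sr_encoder_params(gain = 3, threshold = 0.05,
                                           internal_noise_sd = 0.05),
                         seed = 81)
  expect_equal(which.max(sup$locked_r2), 1L)
})

test_that("sr EEG carries its ground truth and normalizes channel power", {
  env <- gen_speechlike_envelope(30, seed = 82)
  envn <- envelope_series(env$values / max(env$values), 512, "onset")
  masker <- gen_masker_envelope(30, seed = 83)
  p <- sr_encoder_params(gain = 0.6, threshold = 1, internal_noise_sd = 0.05,
                         masker_gain = 2)
  eeg <- gen_sr_eeg(envn, masker, p, seed = 84)
  gt <- attr(eeg, "ground_truth")
  expect_s3_class(gt$kernel, "kernel_spec")
  expect_length(gt$population_response, length(envn$values))
  expect_equal(unname(apply(eeg$data, 1, function(x) sqrt(mean(x^2)))),
               rep(1, 16), tolerance = 1e-9)
})

test_that("synthetic experiments are fully deterministic bookkeeping", {
  grid <- condition_grid(20, 10, 3)
  exp1 <- gen_experiment(2, grid, mode = "linear", duration = 25,
                         base_seed = 90)
  expect_equal(nrow(exp1), 2 * 4)
  expect_equal(anyDuplicated(exp1$seed), 0)
  exp2 <- gen_experiment(2, grid, mode = "linear", duration = 25,
                         base_seed = 90)
  expect_identical(exp1$seed, exp2$seed)
  expect_identical(exp1$eeg[[5]]$data, exp2$eeg[[5]]$data)
  expect_identical(exp1$env[[3]]$values, exp2$env[[3]]$values)
  # artifact injection produces 100 uV excursions where requested
  exp3 <- gen_experiment(1, grid, mode = "linear", duration = 25,
                         base_seed = 91, inject_artifacts_at = 1L)
  rngs <- vapply(seq_len(nrow(exp3)), function(i) {
    max(exp3$eeg[[i]]$data[1, ]) - max(exp2$eeg[[i]]$data[1, ])
  }, numeric(1))
  expect_true(any(rngs > 50))
})

test_that("sr-mode experiments make lower SNR a larger masker drive", {
  grid <- condition_grid(10, 10, 3)
  exp_sr <- gen_experiment(1, grid, mode = "sr", duration = 25, base_seed = 92)
  expect_equal(exp_sr$condition[1], "clear")
  # population output grows with masker drive in the subthreshold regime
  pops <- vapply(seq_len(nrow(exp_sr)), function(i) {
    mean(attr(exp_sr$eeg[[i]], "ground_truth")$population_response)
  }, numeric(1))
  expect_equal(pops[1], 0)                       # clear, subthreshold: silent
  expect_true(all(diff(pops[-1]) > 0))           # drive rises as SNR drops
})
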