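test_that("condition grid reproduces the 21-level experiment ladder", {
  grid <- condition_grid()
  snr <- grid$snr_db[!is.na(grid$snr_db)]
  expect_length(snr, 21L)
  expect_equal(max(snr), 30)
  expect_equal(min(snr), -2, tolerance = 1e-12)
  expect_true(all(diff(snr) < 0))
  expect_equal(diff(snr), rep(-1.6, 20))
  expect_identical(grid$condition[1], "clear")
})

test_that("mix_at_snr hits the requested SNR exactly", {
  set.seed(1)
  speech <- waveform(rnorm(8000), 16000)
  masker <- waveform(rnorm(8000), 16000)
  for (snr in c(20, 0, -2, 7.3)) {
    mix <- mix_at_snr(speech, masker, snr)
    scaled <- mix$samples - speech$samples
    expect_equal(20 * log10(rms(speech) / rms(scaled)), snr, tolerance = 1e-9)
    # scale factor depends only on the RMS ratio and the SNR
    k <- rms(scaled) / rms(masker)
    expect_equal(k, (rms(speech) / rms(masker)) * 10^(-snr / 20),
                 tolerance = 1e-12)
  }
  # unit-RMS special cases: 20 dB -> 0.1, 0 dB -> 1, -2 dB -> 10^0.1
  su <- waveform(speech$samples / rms(speech), 16000)
  mu <- waveform(masker$samples / rms(masker), 16000)
  for (case in list(c(20, 0.1), c(0, 1), c(-2, 10^0.1))) {
    mix <- mix_at_snr(su, mu, case[1])
    expect_equal(rms(mix$samples - su$samples), case[2], tolerance = 1e-9)
  }
})

test_that("mix_at_snr validates its inputs and crops long maskers reproducibly", {
  speech <- waveform(sin(2 * pi * 5 * seq(0, 1, by = 1e-3)), 1000)
  expect_error(mix_at_snr(speech, waveform(numeric(2000), 1000), 0), "zero RMS")
  expect_error(mix_at_snr(waveform(numeric(1001), 1000),
                          waveform(rnorm(2000), 1000), 0), "zero RMS")
  expect_error(mix_at_snr(speech, waveform(rnorm(2000), 999), 0), "rates differ")
  expect_error(mix_at_snr(speech, waveform(rnorm(10), 1000), 0), "shorter")
  long <- waveform(rnorm(5000), 1000)
  m1 <- mix_at_snr(speech, long, 5, seed = 11)
  m2 <- mix_at_snr(speech, long, 5, seed = 11)
  m3 <- mix_at_snr(speech, long, 5, seed = 12)
  expect_identical(m1$samples, m2$samples)
  expect_false(identical(m1$samples, m3$samples))
})

test_that("normalize_mixture implements both normalization schemes", {
  set.seed(2)
  mix <- waveform(rnorm(4000, sd = 0.2), 8000)
  out <- normalize_mixture(mix, "mixture_rms", target_rms = 0.1)
  expect_equal(rms(out), 0.1, tolerance = 1e-9)
  expect_equal(out$samples, mix$samples * (0.1 / rms(mix)), tolerance = 1e-12)
  expect_identical(normalize_mixture(mix, "speech_rms")$samples, mix$samples)
  # clear speech already at target is a fixed point
  fp <- normalize_mixture(mix, "mixture_rms", target_rms = rms(mix))
  expect_equal(fp$samples, mix$samples, tolerance = 1e-12)
  expect_error(normalize_mixture(waveform(c(0, 0), 100), "mixture_rms"),
               "all-zero")
  # mixture_rms commutes with global input scaling
  sc <- waveform(mix$samples * 7, 8000)
  expect_equal(normalize_mixture(sc, "mixture_rms", 0.1)$samples,
               out$samples, tolerance = 1e-12)
})

test_that("spectrally matched noise preserves the magnitude spectrum", {
  set.seed(3)
  speech <- waveform(rnorm(4096), 16000)
  noise <- spectrally_matched_noise(speech, seed = 5)
  expect_equal(length(noise$samples), length(speech$samples))
  expect_lt(max(abs(Mod(fft(noise$samples)) - Mod(fft(speech$samples))) /
                  pmax(Mod(fft(speech$samples)), 1e-12)), 1e-6)
  expect_identical(spectrally_matched_noise(speech, seed = 5)$samples,
                   noise$samples)
  # applying it to its own output reproduces the same magnitude spectrum
  again <- spectrally_matched_noise(noise, seed = 99)
  expect_lt(max(abs(Mod(fft(again$samples)) - Mod(fft(speech$samples))) /
                  pmax(Mod(fft(speech$samples)), 1e-12)), 1e-6)
  # a pure sine stays a pure sine of the same amplitude
  n <- 1024
  sine <- waveform(sin(2 * pi * 8 * (0:(n - 1)) / n), n)
  out <- spectrally_matched_noise(sine, seed = 2)
  mags <- Mod(fft(out$samples))
  expect_equal(mags[c(9, n - 7)] / (n / 2), c(1, 1), tolerance = 1e-9)
  expect_lt(max(mags[-c(9, n - 7)]), 1e-9 * n)
})

test_that("synthetic white and pink noise have the right spectral slopes", {
  white <- synth_noise("white", 2^17, 1000, seed = 4)
  pink <- synth_noise("pink", 2^17, 1000, seed = 4)
  expect_equal(mean(white$samples), 0, tolerance = 1e-9)
  expect_equal(mean(pink$samples), 0, tolerance = 1e-9)
  expect_gt(psd_slope(white), -0.1)
  expect_lt(psd_slope(white), 0.1)
  expect_gt(psd_slope(pink), -1.15)
  expect_lt(psd_slope(pink), -0.85)
  expect_identical(synth_noise("pink", 2^10, 1000, seed = 9)$samples,
                   synth_noise("pink", 2^10, 1000, seed = 9)$samples)
  expect_error(synth_noise("brown", 100, 1000), "arg")
})

test_that("babble equalizes, sums and normalizes talker streams", {
  streams <- lapply(1:12, function(i) synth_noise("white", 8000, 8000, seed = i))
  bab <- make_babble(streams)
  acc <- Reduce(`+`, lapply(streams, function(w) w$samples / rms(w$samples)))
  expect_equal(bab$samples, acc / rms(acc), tolerance = 1e-12)
  expect_equal(rms(bab), 1, tolerance = 1e-12)
  # independent unit-RMS streams sum to about sqrt(12) before normalization
  expect_equal(rms(acc), sqrt(12), tolerance = 0.05 * sqrt(12))
  # coherent case: 12 copies of one stream give back that stream
  cop <- make_babble(rep(streams[1], 12))
  expect_equal(abs(cor(cop$samples, streams[[1]]$samples)), 1, tolerance = 1e-12)
  expect_error(make_babble(streams[1:11]), "at least 12")
})
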