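#' Ground-truth TRF kernel specification
#'
#' A P1-N1-P2-like kernel built from Gaussian deflections, used as the known
#' forward-model kernel in simulations: by default an early positive
#' deflection at 0.06 s, a negative one at 0.11 s, and a late positive one
#' at 0.20 s.
#'
#' @param deflections Tibble/data frame with columns `latency` (s, strictly
#'   increasing), `amplitude` (a.u.) and `width` (s, Gaussian SD, > 0).
#' @param rate Sampling rate of the kernel lag grid (Hz).
#' @param support Lag range `c(min, max)` over which the kernel is nonzero.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(deflections = NULL, rate = 512, support = c(0, 0.4)) {
  if (is.null(deflections)) {
    deflections <- tibble::tibble(
      latency = c(0.06, 0.11, 0.20),
      amplitude = c(1.0, -1.3, 0.8),
      width = c(0.02, 0.03, 0.05)
    )
  }
  deflections <- tibble::as_tibble(deflections)
  if (any(diff(deflections$latency) <= 0)) {
    stop_invalid("deflection latencies must be strictly increasing")
  }
  if (any(deflections$width <= 0)) stop_invalid("deflection widths must be > 0")
  structure(list(deflections = deflections, rate = as.numeric(rate),
                 support = support),
            class = "kernel_spec")
}

#' Evaluate a kernel on a lag grid
#'
#' @param spec A [kernel_spec].
#' @param lags Lags in seconds (default: the kernel's own uniform grid).
#' @return Numeric vector of kernel values; zero outside the support.
#' @export
kernel_values <- function(spec, lags = NULL) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (is.null(lags)) {
    lags <- seq(spec$support[1], spec$support[2], by = 1 / spec$rate)
  }
  k <- numeric(length(lags))
  for (i in seq_len(nrow(spec$deflections))) {
    d <- spec$deflections[i, ]
    k <- k + d$amplitude * exp(-(lags - d$latency)^2 / (2 * d$width^2))
  }
  k[lags < spec$support[1] | lags > spec$support[2]] <- 0
  k
}

# Causal convolution of an envelope with a kernel sampled on the lag grid
# starting at lag 0; output has the length of the envelope.
convolve_kernel <- function(values, spec, rate) {
  k <- kernel_values(spec, seq(0, spec$support[2], by = 1 / rate))
  full <- stats::convolve(values, rev(k), type = "open")
  full[seq_along(values)] / rate
}

# 1/f sensor noise emulating the background of *analysis-ready* EEG: pink
# above the 0.7 Hz high-pass corner of the preprocessing chain, zero below
# (a raw-EEG drift component would never survive preprocessing).
sensor_noise <- function(n, rate, seed, floor_hz = 0.7) {
  half <- n %/% 2L
  n_free <- if (n %% 2L == 0L) half - 1L else half
  phases <- with_seed(seed, stats::runif(n_free, -pi, pi))
  f <- seq_len(n_free) * rate / n
  mag <- ifelse(f < floor_hz, 0, 1 / sqrt(f))
  spec <- complex(real = numeric(n), imaginary = numeric(n))
  spec[2L:(n_free + 1L)] <- mag * exp(1i * phases)
  spec[n:(n - n_free + 1L)] <- Conj(spec[2L:(n_free + 1L)])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / rms(x)
}

# Fixed per-channel gain topography: the evoked response peaks over the
# fronto-central cluster, falls off toward temporal/parietal sites.
channel_gains <- function(labels) {
  g <- stats::setNames(rep(0.4, length(labels)), labels)
  g[names(g) %in% frontocentral_cluster()] <- 1
  g[names(g) %in% c("Fp1", "Fp2", "F7", "F8", "P3", "Pz", "P4")] <- 0.6
  g[names(g) %in% c("M1", "M2")] <- 0
  g
}

#' Generate a speech-like onset envelope
#'
#' Poisson-process onset events at the syllabic rate, each convolved with a
#' positive gamma-shaped onset pulse with a random (gamma-distributed)
#' amplitude.  This emulates the event statistics of story speech at the
#' level the TRF cares about: sparse, non-negative, syllable-rate onsets.
#'
#' @param duration Duration in seconds (>= 25 so that 25 s analysis snippets
#'   can be drawn).
#' @param rate Sampling rate (Hz), matching the preprocessed EEG.
#' @param syllable_rate Mean event rate (Hz), in (1, 10).
#' @param seed Integer seed.
#' @return An [envelope_series] of kind `"onset"`.
#' @export
gen_speechlike_envelope <- function(duration, rate = 512, syllable_rate = 4,
                                    seed = 1L) {
  if (duration < 25) {
    stop_invalid(paste0("duration must be >= 25 s so that 25 s snippets ",
                        "(snippet_scheme) can be extracted"))
  }
  if (syllable_rate <= 1 || syllable_rate >= 10) {
    stop_invalid("syllable_rate must be in (1, 10) Hz")
  }
  n <- as.integer(round(duration * rate))
  values <- with_seed(seed, {
    n_events <- stats::rpois(1, duration * syllable_rate)
    train <- numeric(n)
    if (n_events > 0) {
      at <- sample.int(n, n_events, replace = TRUE)
      amp <- stats::rgamma(n_events, shape = 2, rate = 2)
      for (i in seq_len(n_events)) train[at[i]] <- train[at[i]] + amp[i]
    }
    # 50 ms gamma-shaped onset pulse
    tp <- seq(0, 0.15, by = 1 / rate)
    pulse <- (tp / 0.02) * exp(1 - tp / 0.02)
    out <- stats::convolve(train, rev(pulse), type = "open")[seq_len(n)]
    list(values = pmax(out, 0), n_events = n_events)
  })
  env <- envelope_series(values$values, rate, "onset")
  attr(env, "n_events") <- values$n_events
  env
}

#' Generate a dense masker envelope (multi-talker babble)
#'
#' Sum of several independent speech-like onset envelopes, normalized to a
#' maximum of 1.  With 12 talkers the result is a dense, stationary
#' fluctuation around a positive mean — the envelope signature of 12-talker
#' babble, as opposed to the sparse envelope of a single talker.  Used as
#' the masker drive of the stochastic-resonance encoder.
#'
#' @inheritParams gen_speechlike_envelope
#' @param n_talkers Number of summed talker streams.
#' @return An [envelope_series] of kind `"onset"` with `max(values) == 1`.
#' @export
gen_masker_envelope <- function(duration, rate = 512, n_talkers = 12L,
                                syllable_rate = 5, seed = 1L) {
  acc <- 0
  for (i in seq_len(n_talkers)) {
    acc <- acc + gen_speechlike_envelope(duration, rate, syllable_rate,
                                         seed = child_seed(seed, i))$values
  }
  envelope_series(acc / max(acc), rate, "onset")
}

#' Simulate EEG from a linear forward model
#'
#' Each channel is the known kernel convolved with the onset envelope,
#' scaled by a fixed fronto-central gain topography, plus 1/f (pink) sensor
#' noise at the stated response SNR (per channel, on RMS;
#' `response_snr_db = Inf` gives noiseless data).  The ground-truth kernel
#' is stored in the `"ground_truth"` attribute.
#'
#' @param env An [envelope_series] at the EEG rate.
#' @param kernel A [kernel_spec].
#' @param response_snr_db Evoked-to-noise ratio in dB.
#' @param labels Channel labels (default: the 16 scalp channels).
#' @param seed Integer seed for the sensor noise.
#' @return An [eeg_recording] (reference `"linked_mastoids"`).
#' @export
gen_linear_eeg <- function(env, kernel = kernel_spec(), response_snr_db = -10,
                           labels = setdiff(eeg_channels(), c("M1", "M2")),
                           seed = 1L) {
  stopifnot(inherits(env, "envelope_series"))
  n <- length(env$values)
  evoked <- convolve_kernel(env$values, kernel, env$rate)
  gains <- channel_gains(labels)
  dat <- matrix(0, length(labels), n)
  evoked_rms <- rms(evoked)
  for (ch in seq_along(labels)) {
    sig <- gains[ch] * evoked
    dat[ch, ] <- sig
    if (is.finite(response_snr_db) && gains[ch] > 0) {
      noise <- sensor_noise(n, env$rate, seed = child_seed(seed, ch))
      # a zero kernel leaves pure sensor noise at unit RMS
      noise_rms <- if (evoked_rms > 0) rms(sig) * 10^(-response_snr_db / 20) else 1
      dat[ch, ] <- sig + noise * noise_rms
    }
  }
  rec <- eeg_recording(dat, env$rate, labels, "linked_mastoids")
  attr(rec, "ground_truth") <- list(kernel = kernel, gains = gains)
  rec
}

#' Stochastic-resonance encoder parameters
#'
#' A population of threshold units receives a common drive `g * clear_env +
#' masker_gain * masker_env` plus independent Gaussian noise per unit, and
#' emits `max(drive - threshold, 0)` (rectified-linear, the default) or
#' `drive > threshold` (Heaviside).  With a subthreshold gain
#' (`g * max(env) < threshold`) the envelope is invisible in quiet; a
#' moderate acoustic masker pushes the drive across threshold at envelope
#' peaks and so *creates* envelope-locked output — the stochastic-resonance
#' mechanism.  This is a demonstration model with package-chosen defaults,
#' not a fit to any empirical effect size.
#'
#' @param n_units Number of units in the population (>= 1).
#' @param threshold Firing threshold (drive units).
#' @param internal_noise_sd Per-unit Gaussian noise SD (drive units).
#' @param gain Drive per unit of clear-speech envelope.
#' @param masker_gain Drive per unit of masker envelope.
#' @param output `"relu"` or `"heaviside"`.
#' @return A list of class `sr_encoder_params`.
#' @export
sr_encoder_params <- function(n_units = 50L, threshold = 1,
                              internal_noise_sd = 0.05, gain = 0.6,
                              masker_gain = 0.5,
                              output = c("relu", "heaviside")) {
  output <- match.arg(output)
  if (n_units < 1L) stop_invalid("need at least one unit")
  if (internal_noise_sd < 0) stop_invalid("internal_noise_sd must be >= 0")
  structure(list(n_units = as.integer(n_units), threshold = threshold,
                 internal_noise_sd = internal_noise_sd, gain = gain,
                 masker_gain = masker_gain, output = output),
            class = "sr_encoder_params")
}

#' Population response of the threshold encoder
#'
#' @param clear_env,masker_env Aligned [envelope_series] at the same rate
#'   (`masker_env = NULL` for quiet).
#' @param params An [sr_encoder_params].
#' @param seed Integer seed for the per-unit noise.
#' @return Numeric vector: the population-mean output over time.
#' @export
sr_population_response <- function(clear_env, masker_env = NULL,
                                   params = sr_encoder_params(), seed = 1L) {
  stopifnot(inherits(clear_env, "envelope_series"))
  drive <- params$gain * clear_env$values
  if (!is.null(masker_env)) {
    stopifnot(inherits(masker_env, "envelope_series"))
    if (masker_env$rate != clear_env$rate ||
        length(masker_env$values) != length(clear_env$values)) {
      stop_invalid("clear and masker envelopes must be aligned at one rate")
    }
    drive <- drive + params$masker_gain * masker_env$values
  }
  n <- length(drive)
  nonlin <- function(d) {
    if (params$output == "relu") pmax(d - params$threshold, 0)
    else as.numeric(d > params$threshold)
  }
  if (params$internal_noise_sd == 0) return(nonlin(drive))
  with_seed(seed, {
    acc <- numeric(n)
    for (i in seq_len(params$n_units)) {
      acc <- acc + nonlin(drive + stats::rnorm(n, 0, params$internal_noise_sd))
    }
    acc / params$n_units
  })
}

#' Envelope-locked tracking across a masker sweep
#'
#' For each masker gain, runs the threshold population and measures how much
#' of its output is locked to the clear-speech envelope: the Pearson
#' correlation `tracking_r` between population output and envelope, and the
#' envelope-locked power fraction `locked_r2 = tracking_r^2`.  With a
#' subthreshold gain the sweep shows the canonical stochastic-resonance
#' inverted U (interior maximum at a strictly positive masker gain); with a
#' suprathreshold gain the maximum sits at zero masker and noise only hurts.
#'
#' @param clear_env,masker_env Aligned [envelope_series].
#' @param masker_gains Numeric vector of masker gains to sweep (include 0).
#' @param params An [sr_encoder_params]; its own `masker_gain` is ignored.
#' @param seed Integer seed.
#' @return A tibble with columns `masker_gain`, `tracking_r`, `locked_r2`.
#' @export
sr_masker_sweep <- function(clear_env, masker_env, masker_gains,
                            params = sr_encoder_params(), seed = 1L) {
  out <- purrr::map(seq_along(masker_gains), function(k) {
    p <- params
    p$masker_gain <- masker_gains[k]
    pop <- sr_population_response(clear_env, masker_env, p,
                                  seed = child_seed(seed, k))
    r <- if (stats::sd(pop) == 0) 0 else stats::cor(pop, clear_env$values)
    tibble::tibble(masker_gain = masker_gains[k], tracking_r = r,
                   locked_r2 = r^2)
  })
  purrr::list_rbind(out)
}

#' Simulate EEG from the stochastic-resonance encoder
#'
#' The population response of the threshold encoder is convolved with the
#' ground-truth kernel and projected through the fronto-central gain
#' topography; 1/f sensor noise is added at a fixed absolute level (scaled
#' to the clear-speech evoked reference), and each channel is then
#' normalized to a constant RMS — emulating the fact that overall EEG power
#' is roughly condition-independent while the envelope-locked fraction
#' varies with the masker.
#'
#' @inheritParams sr_population_response
#' @param kernel A [kernel_spec].
#' @param sensor_noise_snr_db Evoked-reference-to-sensor-noise ratio in dB
#'   (`Inf` for no sensor noise).
#' @param normalize_power Scale each channel to unit RMS?
#' @param labels Channel labels.
#' @param seed Integer seed.
#' @return An [eeg_recording]; ground truth (kernel, population response) in
#'   the `"ground_truth"` attribute.
#' @export
gen_sr_eeg <- function(clear_env, masker_env = NULL,
                       params = sr_encoder_params(), kernel = kernel_spec(),
                       sensor_noise_snr_db = 0, normalize_power = TRUE,
                       labels = setdiff(eeg_channels(), c("M1", "M2")),
                       seed = 1L) {
  pop <- sr_population_response(clear_env, masker_env, params,
                                seed = child_seed(seed, 1L))
  n <- length(pop)
  evoked <- convolve_kernel(pop, kernel, clear_env$rate)
  # Noise floor referenced to a fully suprathreshold (linear) response to the
  # clear envelope, so the absolute noise level is condition-independent.
  ref <- rms(convolve_kernel(params$gain * clear_env$values, kernel,
                             clear_env$rate))
  gains <- channel_gains(labels)
  dat <- matrix(0, length(labels), n)
  for (ch in seq_along(labels)) {
    sig <- gains[ch] * evoked
    if (is.finite(sensor_noise_snr_db) && gains[ch] > 0) {
      noise <- sensor_noise(n, clear_env$rate, seed = child_seed(seed, 100L + ch))
      sig <- sig + noise * (gains[ch] * ref * 10^(-sensor_noise_snr_db / 20))
    }
    if (normalize_power && rms(sig) > 0) sig <- sig / rms(sig)
    dat[ch, ] <- sig
  }
  rec <- eeg_recording(dat, clear_env$rate, labels, "linked_mastoids")
  attr(rec, "ground_truth") <- list(kernel = kernel, gains = gains,
                                    population_response = pop)
  rec
}

#' Inject rectangular artifacts into a recording
#'
#' Adds brief large-amplitude (100 microvolt by default) rectangular
#' excursions to all channels at random positions — test material for the
#' artifact-zeroing stage.
#'
#' @param rec An [eeg_recording].
#' @param n_artifacts Number of excursions.
#' @param amplitude Excursion amplitude (microvolts).
#' @param width Excursion duration (s).
#' @param seed Integer seed.
#' @return The modified [eeg_recording].
#' @export
inject_artifacts <- function(rec, n_artifacts = 3L, amplitude = 100,
                             width = 0.05, seed = 1L) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- ncol(rec$data)
  w <- max(1L, as.integer(round(width * rec$rate)))
  starts <- with_seed(seed, sample.int(n - w, n_artifacts))
  for (s in starts) rec$data[, s:(s + w - 1L)] <- rec$data[, s:(s + w - 1L)] + amplitude
  rec
}

#' Generate a complete synthetic experiment
#'
#' One story per participant and condition: a speech-like onset envelope and
#' an EEG recording from either the linear forward model (`mode = "linear"`,
#' SNR-independent kernel — a null world for type-I calibration) or the
#' stochastic-resonance encoder (`mode = "sr"`, where lower acoustic SNR
#' means a larger masker drive: `masker_gain = ref_gain *
#' 10^((10 - snr_db) / 20)`, calibrated so the nominal gain applies at
#' +10 dB; the clear condition has zero masker drive).  Every recording has
#' its own derived seed, so the dataset is bit-reproducible from
#' `(base_seed, parameters)` alone.
#'
#' @param n_participants Number of simulated participants.
#' @param grid Condition tibble from [condition_grid()].
#' @param mode `"linear"` or `"sr"`.
#' @param duration Story duration in seconds (>= 25).
#' @param rate Sampling rate (Hz).
#' @param base_seed Integer master seed.
#' @param params An [sr_encoder_params] (sr mode).
#' @param kernel A [kernel_spec].
#' @param response_snr_db Response SNR for linear mode (dB).
#' @param inject_artifacts_at Optional vector of `participant` indices whose
#'   recordings receive rectangular artifact excursions.
#' @return A tibble with one row per participant x condition: `participant`,
#'   `condition`, `snr_db`, `seed`, and list-columns `env`
#'   ([envelope_series]) and `eeg` ([eeg_recording]).
#' @export
gen_experiment <- function(n_participants, grid = condition_grid(),
                           mode = c("linear", "sr"), duration = 30,
                           rate = 512, base_seed = 1L,
                           params = sr_encoder_params(),
                           kernel = kernel_spec(),
                           response_snr_db = -10,
                           inject_artifacts_at = integer(0)) {
  mode <- match.arg(mode)
  rows <- vector("list", n_participants * nrow(grid))
  k <- 0L
  for (p in seq_len(n_participants)) {
    for (ci in seq_len(nrow(grid))) {
      k <- k + 1L
      seed <- child_seed(base_seed, p, ci)
      env <- gen_speechlike_envelope(duration, rate, seed = child_seed(seed, 1L))
      eeg <- if (mode == "linear") {
        gen_linear_eeg(env, kernel, response_snr_db, seed = child_seed(seed, 2L))
      } else {
        # Drive envelope normalized to max 1 so the threshold is meaningful;
        # the TRF regressor is scale-invariant (z-scored columns).
        env <- envelope_series(env$values / max(env$values), rate, "onset")
        snr <- grid$snr_db[ci]
        p2 <- params
        p2$masker_gain <- if (is.na(snr)) 0 else {
          params$masker_gain * 10^((10 - snr) / 20)
        }
        masker <- if (is.na(snr)) NULL else {
          gen_masker_envelope(duration, rate, seed = child_seed(seed, 3L))
        }
        gen_sr_eeg(env, masker, p2, kernel, seed = child_seed(seed, 2L))
      }
      if (p %in% inject_artifacts_at) {
        eeg <- inject_artifacts(eeg, seed = child_seed(seed, 4L))
      }
      rows[[k]] <- tibble::tibble(
        participant = p, condition = grid$condition[ci],
        snr_db = grid$snr_db[ci], seed = seed,
        env = list(env), eeg = list(eeg)
      )
    }
  }
  purrr::list_rbind(rows)
}
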