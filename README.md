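# speechtrack

Tools for studying how the human EEG tracks the amplitude-onset envelope of
continuous speech as acoustic maskers are added — and for asking why
moderate background noise can *enhance* that tracking.

## The problem

When listeners follow a story, low-frequency EEG activity follows the
acoustic onsets of the speech. The strength of this neural speech tracking
is usually quantified with a **temporal response function (TRF)**: a
lag-indexed linear kernel `w(τ)` mapping the stimulus onset envelope `s(t)`
onto each EEG channel,

```
EEG(t) ≈ Σ_τ w(τ) · s(t − τ) ,   τ ∈ [−0.15, 0.5] s
```

estimated by ridge regression (λ = 10 on z-scored lagged predictors) over
randomly drawn 25 s snippets, with held-out-snippet Pearson correlation as
EEG prediction accuracy. The early TRF deflections (P1, N1, P2) are
summarized as P1−N1 and P2−N1 amplitude differences, which cancel additive
offsets. Across a ladder of signal-to-noise ratios (+30 to −2 dB in 1.6 dB
steps), condition profiles are smoothed over neighboring SNRs, compared
against clear speech with paired *t*-tests under Benjamini–Hochberg FDR, and
characterized by a two-piece broken-stick regression whose breakpoint
minimizes group-level RMSE.

A counterintuitive empirical pattern — tracking *grows* as babble noise is
added at high SNRs — has been attributed to **stochastic resonance**: a
near-threshold input that cannot drive a nonlinear neural population by
itself becomes effective when noise pushes it across threshold. The package
includes a threshold-population encoder that reproduces this signature with
full ground truth.

The package implements the complete chain:

* **Stimuli** — SNR mixing with two RMS-normalization schemes, 12-talker
  babble, speech-spectrum-matched noise (FFT magnitude + random phase),
  white/pink noise, WAV I/O.
* **Envelope** — 30-filter gammatone/ERB cochleagram, 0.6 power-law
  compression, 40 Hz low-pass, half-wave-rectified derivative
  (amplitude-onset envelope), resampling to the EEG rate.
* **EEG preprocessing** — 60 Hz elliptic notch, linked-mastoid re-reference,
  0.7/22 Hz linear-phase FIR band limiting, 512 Hz downsampling, artifact
  zeroing (80 µV range in 0.2 s windows, verified against a brute-force
  oracle), 10 Hz low-pass.
* **TRF** — lagged design matrices, ridge estimation, 50×25 s snippet
  cross-validation, prediction accuracy, cross-correlation alternative.
* **Components** — baseline correction, fronto-central cluster averaging
  (F3, Fz, F4, C3, Cz, C4), group-level P1/N1/P2 latencies, per-participant
  amplitudes in 0.02 s windows.
* **Statistics** — sliding SNR averages, paired tests vs. clear with FDR,
  broken-stick breakpoint fits with per-participant slope *t*-tests.
* **Synthetic data** — speech-like Poisson-onset envelopes, linear
  forward-model EEG with a known P1-N1-P2 kernel and 1/f sensor noise, and
  the stochastic-resonance encoder, all bit-reproducible from seeds.

## A worked example

Simulate one participant's story, estimate the TRF, and extract components:

```r
library(speechtrack)

env <- gen_speechlike_envelope(duration = 120, rate = 512, seed = 3)
eeg <- gen_linear_eeg(env, kernel = kernel_spec(), response_snr_db = -10,
                      seed = 4)

cv <- snippet_crossval(env, eeg, snippet_scheme(50, 25, seed = 5),
                       lambda = 10, lags = c(0, 0.4))
cv
#> <trf_crossval> 50 folds, mean prediction r = 0.2806

trf <- fit_trf_ridge(env, eeg, lambda = 10, lags = c(-0.15, 0.5))
tc  <- baseline_and_cluster(trf)
lat <- find_component_latencies(tc)
component_amplitudes(tc, lat)
#> # A tibble: 1 × 8
#>   p1_latency n1_latency p2_latency   p1_amp   n1_amp  p2_amp    p1n1    p2n1
#>        <dbl>      <dbl>      <dbl>    <dbl>    <dbl>   <dbl>   <dbl>   <dbl>
#> 1     0.0488      0.113      0.203 0.000649 -0.00120 0.00112 0.00185 0.00232
```

The prediction accuracy (`r ≈ 0.28`) is the Pearson correlation between
TRF-predicted and observed EEG on held-out snippets, averaged over folds and
the fronto-central cluster — the realistic order of magnitude when the
envelope-locked response sits 10 dB below the sensor noise. The component
table gives the group-window latencies (s) and the P1−N1 / P2−N1 amplitude
differences used for condition-level statistics.

The stochastic-resonance signature in three lines:

```r
envn   <- envelope_series(env$values / max(env$values), 512, "onset")
masker <- gen_masker_envelope(120, seed = 6)
sr_masker_sweep(envn, masker, c(0, 0.5, 1, 2, 4.5, 10),
                sr_encoder_params(gain = 0.6, threshold = 1), seed = 7)
#> # A tibble: 6 × 3
#>   masker_gain tracking_r locked_r2
#>         <dbl>      <dbl>     <dbl>
#> 1         0       0        0
#> 2         0.5     0        0
#> 3         1       0.0982   0.00964
#> 4         2       0.123    0.0151
#> 5         4.5     0.0783   0.00613
#> 6        10       0.0346   0.00119
```

With the subthreshold gain, envelope-locked output is zero in quiet, peaks
at an intermediate masker level, and falls again when the masker dominates —
the inverted U that only a nonlinearity can produce.

End-to-end runs (simulate → envelopes → TRFs → components → statistics) go
through `pipeline_config()` and `run_pipeline()`; every result type is a
tibble with `tidy()`, `glance()` and `autoplot()` methods.

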