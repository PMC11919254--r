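---
title: "Methods: envelope tracking, TRF estimation, and the noise-benefit model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: envelope tracking, TRF estimation, and the noise-benefit model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(speechtrack)
```

This vignette documents the models, parameter choices and numerical
conventions behind `speechtrack`, in the spirit of a statistical methods
appendix. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The analysis chain

The package realizes one fixed processing order:

1. **Stimulus construction** — a masker (12-talker babble, speech-matched
   noise, white or pink noise) is scaled against the speech so that the
   broadband RMS ratio equals the requested SNR, then the mixture is
   normalized under one of two schemes (`mixture_rms`: constant overall
   level, speech level falls with SNR; `speech_rms`: constant speech level,
   overall level rises).
2. **Onset envelope of the clear speech** — a 30-filter gammatone
   cochleagram on ERB-spaced centers, Hilbert-magnitude sub-band envelopes,
   power-law compression with exponent 0.6, band averaging, a fourth-order
   40 Hz Butterworth low-pass, the first difference scaled by the sampling
   rate with negative values set to zero, and resampling to 512 Hz.
   Envelopes are always computed from the *clear* speech, also for masked
   conditions; the pipeline enforces this by construction.
3. **EEG conditioning** — 60 Hz elliptic notch (zero-phase), linked-mastoid
   re-reference, 0.7 Hz high-pass (2449-tap Hann FIR) and 22 Hz low-pass
   (211-tap Kaiser FIR) with exact group-delay compensation, decimation to
   512 Hz, an identity ICA hook, artifact zeroing (any channel range
   > 80 µV within 0.2 s zeroes that window in all channels), and a 10 Hz
   251-tap Kaiser low-pass.
4. **TRF estimation** — ridge regression of each EEG channel on the lagged
   onset envelope; 50 random 25 s snippets per story, each held out once,
   trained on all snippets that do not overlap the held-out one; prediction
   accuracy is the held-out Pearson correlation; for component analysis the
   TRF is estimated over lags −0.15 to 0.5 s, averaged over folds,
   baseline-corrected (−0.15 to 0 s), and averaged over the fronto-central
   cluster F3, Fz, F4, C3, Cz, C4.
5. **Components and statistics** — P1/N1/P2 latencies from the
   across-participant mean time course, per-participant amplitudes as 0.02 s
   window means, P1−N1 and P2−N1 differences; sliding averages over 3 (or 4)
   neighboring SNRs; paired *t*-tests against clear speech with
   Benjamini–Hochberg FDR; broken-stick regression with per-participant
   slope *t*-tests.

## 2. The ridge convention and why it matters

The TRF solves, per channel,

$$ \left( \tfrac{1}{n-1} X_z^\top X_z + \lambda I \right) w_z
   = \tfrac{1}{n-1} X_z^\top y_c $$

where \(X_z\) has z-scored columns and \(y_c\) is the mean-centered channel.
Normalizing the scatter to a correlation matrix (unit diagonal) makes the
fixed \(\lambda = 10\) commensurate with unit predictor variance, hence a
data-size-independent smoother. This choice is not cosmetic: against a raw
scatter matrix with diagonal entries of order \(n \approx 6\times 10^4\), a
fixed \(\lambda = 10\) is numerically void, and the strongly autocorrelated
onset envelope then yields ill-conditioned, noise-dominated weight
estimates — the acceptance check that the estimated TRF correlates > 0.95
with the true simulation kernel at −10 dB response SNR fails by a wide
margin. Weights are mapped back to the raw envelope scale (divided by the
column SDs) so that at \(\lambda = 0\) a noiseless simulation is recovered
exactly; the convention is stored in `TRFModel$normalization`.

Cross-validated training accumulates per-snippet cross-products
\(X^\top X\), \(X^\top y\), column sums and counts, which is algebraically
identical to concatenating the training snippets but avoids materializing
them. The lag grid contains every integer sample shift whose lag lies inside
the requested window, so 0–0.4 s at 512 Hz gives 205 columns; the analysis
grid then starts at −0.148 s, and the baseline window check accepts a grid
that reaches the window to within one sample. Lagged columns are zero-padded
at the story edges.

## 3. Filter realizations

* **Notch**: `signal::ellipord` cannot design band-stops, so the notch is a
  fixed fourth-order elliptic band-stop (0.25 dB passband ripple, 80 dB
  stopband, corners at 57 and 63 Hz) whose measured response exceeds 80 dB
  suppression across 59.5–60.5 Hz in a single pass; `filtfilt` makes it
  zero-phase. The numerator is rescaled so the DC gain is exactly 1
  (recentring the equiripple band), because drift and slow potentials must
  pass unchanged. Higher orders were rejected: beyond eight poles the
  direct-form transfer function loses precision and the realized stopband
  *shrinks* (an order-5 design measured ~45 dB instead of its nominal 80).
* **FIR band limiting**: linear-phase designs applied by convolution with
  both-sided zero padding and integer group-delay removal, so a delta input
  keeps its peak at the same sample (tested at ±1 sample). The high-pass
  taps are adjusted to sum exactly to zero — the windowed design alone
  leaves a DC gain around −33 dB, and a high-pass that passes DC at that
  level visibly contaminates baseline windows. Kaiser windows use
  β = 5.653 (≈ 60 dB sidelobes) at the stated 211/251-tap lengths.
* **Envelope resampling** uses band-limited linear interpolation on the time
  grid rather than a polyphase resampler: the envelope is already low-passed
  at 40 Hz, far below the 256 Hz Nyquist of the 512 Hz target, where the
  interpolation error is negligible; interpolation is delay-free and gives
  exact control of the output length.

The cochleagram itself is a frequency-sampled gammatone bank: each band
multiplies the spectrum by the fourth-order gammatone magnitude
\([1 + ((f-f_c)/b)^2]^{-2}\), \(b = 1.019\,\mathrm{ERB}(f_c)\), on the
positive frequencies only, so one inverse FFT per band returns the analytic
signal and its modulus is the Hilbert envelope. The realization is
zero-phase and exactly linear in the input, which makes the compression
homogeneity test (`input × c ⇒ bands × c^0.6`) exact. Band edges default to
20 Hz–10 kHz; filter shape and edges are configurable because the
auditory-periphery literature does not pin them down.

Derivative order: the onset envelope takes its first difference *before*
resampling (at the audio rate), matching the stated processing order. Note
that rectification and resampling do not commute, so the onset envelope does
not exactly equal the rectified difference of the already-resampled
amplitude envelope; the internal-consistency test therefore verifies the
identity at the audio rate (`eeg_rate = NULL`), where it is exact.

## 4. Artifact zeroing: two routes, bit-exact

The production path computes per-channel sliding ranges with a monotonic
double-ended queue in C++ (O(n)) and unions flagged windows with a coverage
array. `artifact_zero_reference()` recomputes every window's max and min
from scratch (O(n·w)) and marks windows one at a time. The two must agree
bit-exactly; the test suite and the acceptance script check 50 random
18-channel, 10⁵-sample recordings. The threshold is strict (`>` 80 µV), so
an excursion of exactly 80 µV survives, and flagged windows are zeroed in
*all* channels (the conservative reading of per-channel detection); zeroing
only the offending channel would leave cross-channel regression structure
intact for the TRF and is deliberately not the default.

## 5. Statistics: conventions and degenerate inputs

* Sliding averages output the window's center SNR for odd windows and the
  mean SNR for even windows; on the 21-level grid (+30 to −2 dB, 1.6 dB
  steps) the 3-neighbor average spans +28.4 to −0.4 dB with 19 conditions.
* The broken-stick fit grid-searches interior condition SNRs; both pieces
  include the breakpoint sample; pieces are independent lines (no
  continuity constraint), matching separate per-piece slope tests. RMSE ties
  are broken toward the highest SNR, with a small relative tolerance so that
  floating-point noise on exactly linear data cannot masquerade as a
  minimum.
* `slope_ttest` returns \(t = 0, p = 1\) for all-zero slopes (the natural
  limit) but raises an error for zero variance around a nonzero mean, where
  *t* is genuinely undefined.
* FDR flags are `p.adjust(p, "BH") <= q`; Benjamini–Yekutieli is available
  via `method = "BY"`. The BH flags are verified against a brute-force
  step-up enumeration on 1000 random p-vectors.

The breakpoint-recovery simulation uses a rise-then-decline profile (both
pieces carry slope). With a perfectly flat second piece the breakpoint is
identified from one side only and the recovery probability at the simulated
noise level sits almost exactly at the acceptance boundary — a coin flip at
200 simulations — whereas the two-sloped profile is comfortably
identifiable. The flat case remains available to users; it is simply not a
well-posed recovery benchmark.

## 6. The synthetic world

`gen_speechlike_envelope()` draws Poisson onset events at the syllabic rate
(default 4 Hz), gives each a gamma-distributed amplitude, and convolves with
a 50 ms gamma-shaped pulse. This reproduces the features the TRF cares
about — sparse, non-negative, syllable-rate onsets with realistic
autocorrelation — and nothing else: no prosodic rhythm, no spectral content,
no co-articulation. Passing tests on this generator therefore demonstrate
correctness of the estimation machinery, not robustness to every property of
real speech.

`gen_linear_eeg()` convolves a known P1-N1-P2 kernel (Gaussian deflections
at 0.06, 0.11, 0.20 s with amplitudes +1.0, −1.3, +0.8) with the envelope,
projects it through a fixed fronto-central gain topography, and adds 1/f
sensor noise at a stated response SNR (RMS ratio per channel; −10 dB
default, i.e. noise power ten times the evoked power — the regime where a
cross-validated prediction r around 0.3 is expected). The sensor noise is
pink *above a 0.7 Hz floor and zero below*: it models the background of
analysis-ready EEG, which has passed the 0.7 Hz high-pass. Unbounded 1/f
power below 0.7 Hz would simulate a raw recording that no TRF analysis ever
sees, and it dominates the regression so completely that recovery targets
become meaningless.

### The stochastic-resonance encoder

A population of `n_units = 50` rectified-linear threshold units receives a
common drive `g·env_clear + m·env_masker` plus per-unit Gaussian noise
(σ = 0.05 drive units); the population mean is the output. Envelopes are
normalized to a maximum of 1 so the threshold θ = 1 is interpretable:
`gain = 0.6` is subthreshold (the clear envelope alone never fires the
population), `gain = 3` with θ = 0.05 is suprathreshold. The masker drive
uses a *dense* envelope — the sum of 12 independent speech-like streams,
i.e. 12-talker babble, which fluctuates around a positive mean — because a
sparse single-talker masker rarely coincides with speech onsets and cannot
dither the drive across threshold.

Envelope-locked output is measured as the squared Pearson correlation
between population output and clear envelope (`locked_r2`, the locked power
*fraction*). The fraction, not the raw locked power, is the right sweep
metric for a ReLU population: raw locked power saturates monotonically as
the masker grows (once everything is above threshold the system is linear
with envelope coefficient g), so only a normalized measure can show the
decline at strong masking, and only it puts the suprathreshold maximum at
zero masker. For the same reason `gen_sr_eeg()` normalizes each channel to
unit RMS after adding sensor noise — overall EEG power is roughly
condition-independent in practice, while the envelope-locked *fraction*
varies — so the downstream P1−N1 difference inherits the inverted-U shape.
The masker-gain sweep used in verification is
{0, 0.25, 0.5, 1, 1.5, 2, 3, 4.5, 7, 10}, spanning quiet through full
saturation so the decline past the optimum is visible inside the grid. The
downstream P1−N1 sweep is averaged over five seeded runs with group-level
latencies: the P1−N1 of a pure-noise TRF is positively biased in any single
run (a maximum minus a minimum of noise), so a one-run sweep can spuriously
peak at zero masker. In
`gen_experiment(mode = "sr")`, lower acoustic SNR maps to a larger masker
drive via `m(snr) = m_ref · 10^{(10 − snr)/20}`, calibrated so the nominal
gain applies at +10 dB.

All encoder parameters are package defaults chosen to demonstrate the
mechanism; they are not fitted to any empirical effect size, and no
quantitative claim about human data rests on this module.

## 7. Problem sizes used in verification

The test-suite and acceptance-script simulations use: 12 stories × 2 min at
512 Hz with 50 × 25 s snippet folds for kernel recovery; 22 simulated
participants (one 2-min story each) for the prediction-accuracy group test;
50 recordings of 10⁵ samples × 18 channels for the artifact oracle; 200
breakpoint simulations with 22 participants and 5000 null slope tests; and
20 seeded stochastic-resonance sweeps per gain regime. These sizes make
every stochastic check stable at its stated threshold while a full
verification run completes in minutes on a single core.

## 8. Known limitations

* The gammatone realization is zero-phase and frequency-sampled; a causal
  time-domain gammatone would shift sub-band envelopes by its group delay.
  The filter shape is swappable behind `cochleagram_params()`.
* ICA cleanup is an interface hook only (`preprocess_eeg(ica_hook = …)`);
  the package ships no decomposition.
* The EDF/BDF reader adapter is not included; recordings enter either from
  the synthetic generators or through the package's plain-text container
  (`read_eeg`/`write_eeg`), and audio through WAV.
* rmANOVA-style factorial tests (masker type × SNR × normalization) are out
  of scope; `tidy()` output is formatted for external ANOVA software.
* The synthetic envelope generator does not model prosody, speaker identity
  or semantics; conclusions about those properties of real speech cannot be
  drawn from simulations alone.
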