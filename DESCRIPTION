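Package: speechtrack
Title: Neural Speech Tracking with Temporal Response Functions Under Acoustic Masking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how the human EEG tracks the amplitude-onset
    envelope of continuous speech as background maskers are added.  Implements
    masker synthesis (multi-talker babble, speech-matched noise, white and pink
    noise) and SNR mixing with two RMS-normalization schemes, a gammatone/ERB
    auditory-periphery onset-envelope model, an EEG preprocessing chain (line-noise
    notch, linked-mastoid re-reference, FIR band limiting, artifact zeroing,
    downsampling), ridge-regularized temporal response function (TRF) estimation
    with snippet-based cross-validation and Pearson prediction accuracy, P1-N1/P2-N1
    component quantification, condition-level statistics (sliding SNR averages,
    paired tests with FDR, broken-stick breakpoint regression), and a synthetic-data
    generator with a stochastic-resonance threshold-population encoder that gives
    every stage a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    generics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
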