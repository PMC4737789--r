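---
title: "Acoustic CAD scoring: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic CAD scoring: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem and the signal model

Post-stenotic turbulence in a partially occluded coronary artery produces
faint diastolic murmurs. Because coronary flow peaks in diastole and the
heart is otherwise quiet between the third (S3) and fourth (S4) heart
sounds, that interval — the *diastasis* — is the natural analysis window for
an acoustic test of obstructive coronary artery disease (CAD). `cadsound`
implements the full chain from a single-channel chest-wall phonocardiogram
to a 0–100 point acoustic score and the statistics used to evaluate such a
score against a clinical reference standard.

The pipeline is:

1. **Band-limiting** to 20–1000 Hz, the range carrying diastolic heart-sound
   energy.
2. **Cycle detection** without ECG gating: a 30–150 Hz Hilbert envelope
   isolates the loud valve sounds S1/S2, an autocorrelation of the envelope
   (decimated to 200 Hz; 5 ms resolution is ample) estimates the beat
   period over 40–120 bpm, peaks are picked, and S1 vs S2 is resolved by
   interval ordering — systole (S1→S2) is the shorter intra-beat interval.
   S3 and S4 are then sought in a 20–60 Hz envelope inside physiologic
   sub-windows of each diastole.
3. **Diastasis extraction**: the window runs from the end of S3 (onset plus
   a nominal 60 ms) to the S4 onset; when S3 is undetected the start falls
   back to `s2 + 0.15·RR` (mid-diastole), and when S4 is undetected the
   window ends 50 ms before the next S1. Windows shorter than 128 ms are
   flagged *short diastasis*; a recording is short-diastasis when more than
   half of its accepted windows are (or none were accepted).
4. **Four acoustic measures**:
   * **FPR** — `log10` ratio of 20–150 Hz to 150–1000 Hz diastolic power
     (Welch average of 128 ms Hann segments, 50 % overlap). The 150 Hz
     split reflects the observed concentration of disease-related power
     below 150 Hz; it is configurable.
   * **PCASpec** — projection of the subject's mean dB spectrum onto the
     first principal component of the training cohort's mean-centred dB
     spectra. The loading's sign is fixed so its mean below 150 Hz is
     positive, making "diseased projects higher" the stable orientation.
   * **AMI** — auto-mutual information: the signal is decimated to
     2000 Hz, discretized into 16 equiprobable amplitude bins, and the
     histogram mutual information between the signal and its lagged copy
     (lags 1–25 samples, 0.5–12.5 ms) is averaged, in bits. Equiprobable
     binning makes the measure invariant to amplitude scaling.
   * **S4Amp** — the peak of the 20–60 Hz envelope in the S4 search region
     (0.20–0.05 s before the next S1), normalized by the median S1 envelope
     peak, removing sensor gain.
5. **Scoring** — a Fisher linear discriminant (pooled within-class
   covariance) on the four measures, with a reduced AMI + S4Amp
   discriminant for short-diastasis recordings, since FPR and PCASpec
   require at least one 128 ms window. Each branch carries an affine
   calibration chosen so training scores have mean 25 and SD 12 before
   clipping to [0, 100] — this reproduces the deployed score scale, whose
   reference group means are 21.3 / 29.7 / 32.8 points with SDs near 11–13.
   Score categories are low (≤ 20), intermediate (20, 30], high (> 30);
   boundaries belong to the lower category, consistent with how the
   negative predictive value of "score ≤ 20" is defined.

## Evaluation suite

`roc_auc()` computes the tie-corrected Mann–Whitney AUC with DeLong
confidence intervals, and `compare_auc_paired()` the paired DeLong test;
both are validated against an exhaustive pair-count oracle and against
pROC in the test suite. `liu_cutpoint()` maximizes sensitivity ×
specificity over midpoints between consecutive sorted scores, ties broken
toward the lower threshold, with "positive" meaning *strictly greater*
than the threshold (matching the "> 30" / "≤ 20" usage). Categorical NRI
uses the four pre-test risk categories (< 10, 10–30, 30–60, ≥ 60 %; each
boundary belongs to the upper category) with asymptotic confidence
intervals; continuous NRI and IDI follow the standard reclassification
formulas. `cross_validate()` implements repeated stratified ten-fold
cross-validation (default 20 × 10), pooling held-out scores within each
repeat before computing one AUC per repeat.

Clinical pre-test probability uses a logistic model on age, sex, and
chest-pain type in the updated Diamond–Forrester tradition. The exact
published coefficient table is not reprinted here; the shipped default has
that functional form with plausible magnitudes and is deliberately
configuration, not code — analyses needing exact published values pass
their own table, and all package tests of exact probabilities do so. The
combined model is a logistic regression of disease on the logit pre-test
probability and the raw score: the simplest fusion consistent with
reporting a combined AUC, NRI, and IDI.

### A note on the packaged reclassification counts

The packaged reference cross-tab (n = 228) prints its nonevent net move as
"55 − 36 = 20 (12 %)", which is internally inconsistent: 55 − 36 = 19 and
19/165 = 11.5 %. `reproduce_table3()` reports the formula values and flags
the discrepancy in its `note` column rather than silently matching the
printed numbers; the total categorical NRI (12/63 + 19/165 = 0.306) still
rounds to the printed 0.31.

## The simulator: what it emulates, and what it does not

`simulate_pcg()` builds a waveform as a per-beat sum of Gaussian-enveloped
tone bursts (S1 ≈ 55 Hz / 70 ms, S2 ≈ 90 Hz / 60 ms, S3 ≈ 32 Hz and
S4 ≈ 36 Hz at 50 ms, S4 centred 120 ms before the next S1; systole
duration `0.31·√RR`), plus diastasis-gated coloured murmur noise, plus a
white floor 50 dB below S1. The two murmur gains mirror the two spectral
disease signatures — elevated low-frequency (< 150 Hz) power and faint
high-frequency (200–500 Hz) microbruits — and are calibrated so a +10 dB
gain step raises measured diastasis band power by 10 dB (the murmur
reference level sits 20 dB above the white floor, keeping floor
contamination below 0.05 dB). Landmark times are returned exactly, so
detector accuracy is testable against ground truth. The audio-cohort
default plants +6 dB / +3 dB murmur excesses in disease — a direction, not
a measured clinical magnitude, chosen to be clearly detectable at the
40-subjects-per-group scale used in testing.

The simulator does **not** emulate breathing noise, ambient transients,
sensor transfer functions, heart-rate variability within a recording,
murmurs of valvular origin, or realistic inter-subject spectral
variability. A green end-to-end test therefore demonstrates that the
pipeline is internally consistent and detects a planted diastolic murmur
effect; it says nothing about sensitivity or specificity on clinical
recordings.

`simulate_cohort()` works at the score level: per disease group
(124 / 41 / 63 subjects), acoustic scores and pre-test probabilities are
drawn from a Gaussian copula whose group margins match the reference
cohort's printed means and SDs, truncated to their natural ranges by
inverse-CDF sampling. The within-group latent correlation is solved by
moment matching so the whole-cohort Pearson correlation hits the 0.36
target — the group-mean structure already contributes part of the
covariance, and the solve accounts for it; truncation bias is ignored
(small, and checked stochastically in the tests). Age, sex, and chest-pain
covariates are back-filled consistently with the drawn probability by
inverting the logistic pre-test model for age given sampled sex and
symptom type.

## Numerical and design choices

* **Band-limiting filter.** A zero-phase FFT mask with raised-cosine
  edges (half-octave ramp below 20 Hz, 10 % ramp above 1000 Hz) instead of
  an IIR filter. Two properties forced this choice: re-applying the filter
  must be numerically idempotent (an order-4 zero-phase Butterworth loses
  ~4 % RMS of broadband signal on a second pass through transition-band
  re-attenuation), and — more importantly — a sharp low edge rings: a
  narrow 20 Hz transition smears the loud S1 bursts several hundred
  milliseconds into the quiet diastolic floor, corrupting exactly the
  spectrum the score is built on. The widened smooth ramps keep the
  impulse response short. Butterworth filtering is still used where
  ringing is irrelevant (envelope extraction, murmur synthesis).
* **S3/S4 detection gate.** An interior 20–60 Hz envelope peak must exceed
  4× the median envelope of that beat's own diastole. The baseline is
  local because diastolic murmur raises the floor — a global threshold
  either misses S3/S4 in murmur-rich recordings or fires on noise in quiet
  ones. Only interior maxima that dominate the search region's right edge
  count, because the narrowband envelope of the *upcoming* S1 rises
  monotonically there and would otherwise fake an S4.
* **AMI on short-diastasis recordings.** Strict windows can be shorter
  than the 64 ms AMI minimum (or degenerate) at high heart rates, yet the
  reduced score needs AMI; it then falls back to the broader mid-diastolic
  interval from `s2 + 0.10 s` to 50 ms before the next S1.
* **Quality gates** quantify the three clinical exclusion labels:
  arrhythmia if the RR coefficient of variation exceeds 0.12 or the rate
  exceeds 85 bpm; excess noise if more than half the candidate windows
  carry mean envelope power above 4× the recording's median envelope
  power (median over samples, not over windows — a majority of noisy
  windows must not be able to shift the baseline); weak signal if the
  median S1 envelope peak is less than 6 dB above the median envelope.
  All thresholds are configuration.
* **Degenerate inputs.** Zero-variance AMI segments return 0 with a
  warning; an all-short recording routes to the reduced score; identical
  training spectra raise a degenerate-PCA error; a singular pooled
  covariance falls back to a ridge (1e-6) fit with a warning; logistic
  separation in the combined model falls back to a lightly ridge-penalized
  IRLS fit with a warning.
* **Calibration scale** (mean 25, SD 12) and the 0–100 clip are
  configuration; the affine form was chosen because the deployed score's
  mapping is unspecified and an affine map is the simplest that reproduces
  the reference scale's group means and spreads.

## Problem sizes used in the shipped tests

The test suite synthesizes all of its data: single recordings of 12–25 s
at 8 kHz; the end-to-end audio cohort uses 40 subjects per group at 20 s
each; the distribution-level AUC check uses 200 replicates of the
228-patient score cohort; cross-validation checks use 20 × 10-fold on
228-row feature tables. These sizes give stable Monte-Carlo behaviour for
every asserted tolerance while keeping a full test run in the minutes
range on one core.

## Known limitations

* The segmentation thresholds are tuned for the simulator's clean signal
  class; clinical recordings with breathing artifacts, rubs, or ectopy
  will need the configuration surface (and plausibly a better detector).
* The exact formulas behind the deployed FPR and PCASpec measures are not
  public; the implementations here are principled reconstructions and are
  exposed as configuration.
* The default pre-test coefficient table approximates the published
  updated model's form but is not the published table.
* NRI/IDI confidence intervals are asymptotic; no bootstrap option is
  wired in yet.
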