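---
title: "Decoding overt speech from cortical activity: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding overt speech from cortical activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Speech brain-computer interfaces aim to reconstruct audible speech, frame by
frame, from ongoing cortical activity. Linear decoders are attractive for this
because they can run within milliseconds. `ecogspeech` implements a complete
offline evaluation pipeline for that idea: vocoder analysis and resynthesis of
the acoustic signal, spectral feature extraction from multichannel cortical
recordings, estimation of a participant's articulatory trajectories by dynamic
time warping (DTW) transfer from a reference articulography corpus, five linear
decoders, a feedforward articulatory-to-acoustic synthesizer, and a
cross-validated statistical evaluation with chance levels.

Because paired cortical/articulatory/audio recordings of this kind are not
publicly available, the package ships a synthetic-data generator that emulates
the *structure* of such a study with known ground truth. Every stage of the
pipeline is tested against that ground truth.

## Speech representation

Audio is represented by a source-filter vocoder at a 100 Hz frame rate:

* **Spectral envelope**: an order-24 mel cepstrum (25 coefficients
  $c_0..c_{24}$). The log amplitude spectrum of each 400-sample Blackman
  window (22,050 Hz audio, 220-sample frame shift, 1,024-point FFT,
  $10^{-4}$ periodogram floor) is evaluated on an all-pass warped frequency
  axis with warping constant $\alpha = 0.455$, which approximates the mel
  scale at this sampling rate, and truncated to its first 25 cosine
  coefficients. The native ~100.23 Hz frame rate is resampled to exactly
  100 Hz by shape-preserving piecewise-cubic (pchip) interpolation.
* **Source**: F0 in Hz per frame, 0 when unvoiced, constrained to 80–300 Hz.
  The estimator is a normalized-autocorrelation tracker (unbiased lag
  normalization, 2.5 kHz low-pass before analysis, octave-error guard);
  voiced runs shorter than 50 ms are discarded. F0 is resampled by
  nearest-neighbor interpolation to preserve voicing discontinuities.
* **Synthesis**: each frame's warped envelope, built from the cosine
  expansion of $c_0..c_{24}$, filters an excitation signal — an impulse
  train at period $\mathrm{pitch} = f_s / F0$ samples when voiced, white
  noise when unvoiced — with zero-padded overlap-add so the zero-phase
  envelope response adds as a linear convolution. Output is peak-normalized,
  soft-limited, and set to −20 dBFS.

A full analysis–synthesis–analysis roundtrip on a time-varying synthetic vowel
reproduces every coefficient with correlation above 0.9 (see
`test-acoustics.R`); the residual is the usual vocoder limit — the envelope is
only observable at the harmonics of F0, and frame energy jitters with the
impulse/window alignment.

## Neural features

Recordings are re-referenced by the **common median reference** (the
across-channel median is subtracted at every sample), which removes signals
shared by all contacts such as mains interference. Per channel, 21 features
are computed at 100 Hz: short-time power in twenty 10 Hz bands from 0 to
200 Hz (200 ms Hamming windows, 10 ms shift, periodogram), plus the raw
signal band-passed to 0.5–5 Hz. The band-pass is implemented as a
high-pass/low-pass cascade: a single 8th-order band-pass with such a narrow
normalized band is numerically unstable at a 1000 Hz sampling rate. The
0.5–5 Hz feature is computed after median referencing, on the same
preprocessed signal as the spectra (the alternative order is not
distinguishable on synthetic data; we state it as an assumption).

**Context and delay.** To decode the speech frame at time $t$, neural frames
$x(t+\tau-k)\dots x(t+\tau+k)$ are concatenated. Negative delays $\tau$ shift
the window into the past. Context lengths quoted in ms map to odd frame
counts (50 ms → ±2 frames, 110 ms → ±5, 210 ms → ±10). Boundary frames use
edge replication so that per-sentence correlations are computed on full
sentences.

## Articulatory transfer by DTW

The reference corpus carries 14 midsagittal articulatory features (9 3-D
sensors, lip corners dropped, 2 principal components per remaining sensor).
To estimate the patient's articulation, each reference sentence is aligned to
the patient's rendition of the same sentence by DTW on a 27-dimensional
acoustic feature vector: the 25 mel coefficients divided by the sentence's
max $|c_0|$, F0 divided by its sentence maximum, and a 0/1 speech flag, with
speech and voiced runs shorter than 50 ms zeroed. The sample-wise distance is
the *sum of squares* over these 27 features, exactly as printed in the source
method (no square root; a `use_sqrt` switch allows the variant). Both tracks
are brought to the patient length by symmetric-padding + pchip resampling
before alignment; the optimal monotone path (steps {(1,0),(0,1),(1,1)}, ties
preferring the diagonal) then carries the reference articulation onto patient
timing, aggregating many-to-one matches by the mean ("last match"
selectable). DTW is run per sentence pair.

## Linear decoders

All five decoders share one preprocessing pipeline, fitted on training data
only, in this order: (1) z-score inputs and targets; (2) apply the delay;
(3) optionally reduce the *delayed, un-concatenated* neural features by PCA
(never the targets); (4) concatenate the temporal context. PLS skips PCA and
performs its own reduction after context concatenation. The decoders:

* **OLS** — solved by pivoted QR of the design itself (forming $X^\top X$
  squares the condition number and destroys weakly excited directions);
  minimum-norm solution with a warning when rank-deficient.
* **Ridge** with $\lambda$ chosen by (a) the **L-curve** corner (maximum
  curvature of the spline-smoothed log residual-norm vs log solution-norm
  curve over a 25-point grid, $10^{-4}..10^4$), (b) inner 5-fold
  **cross-validation** minimizing validation MSE pooled over outputs, or
  (c) the same CV run **per output column**. The penalty acts on
  standardized predictors (as is standard ridge practice, e.g. glmnet);
  inner CV folds are contiguous blocks because interleaved folds would leak
  through the strong autocorrelation of adjacent frames and bias $\lambda$
  low. MSE (not correlation) is the selection criterion.
* **PLS2** — NIPALS with deflation (tolerance $10^{-6}$, max 500
  iterations), one shared latent space for all outputs, with the equivalent
  linear weight matrix exposed.

## Articulatory-to-acoustic synthesizer

A feedforward network predicts the 25 mel coefficients of frame $s$ from
articulatory frames $s-10..s+1$ (12 × 14 = 168 inputs; a single 10 ms
look-ahead). Defaults follow the study design: 3 hidden layers of 512 tanh
units, MSE loss, Adam, 25% dropout, batches of 32, early stopping with
patience 20 on a random 80/10/10 frame split, best-epoch weights restored.
Learning rates (not given in the source) default to $10^{-3}$ for training
and $10^{-4}$ for fine-tuning, the smaller step preserving pretrained
structure. Inputs and targets are z-scored with training-split statistics
inside this module. Fine-tuning restarts the same loop from the pretrained
weights (the input network object is never modified) and, inside
cross-validation, respects the outer fold boundaries.

## Evaluation framework

Sentences are split into 10 folds (seeded, stratified by speaking condition
to balance folds; the source states only "randomly split"). Direct decoding
predicts the 25 mel coefficients and F0; indirect decoding predicts the 14
articulatory features on *all* sentences with the fold's decoder, fine-tunes
the synthesizer on the training folds' decoded articulation (or uses it
as-is), and predicts mel on the test fold; F0 is always decoded directly.
Metrics are Pearson r and MSE per feature over entire sentences — one value
per sentence. Predictions without fine-tuning are evaluated against the
DTW-warped reference mel; everything else against the patient's features.

**Chance levels** permute the neural feature frames once, uniformly across
the whole corpus (10 ms frames, targets untouched, seed recorded), then run
the identical pipeline. **Statistics**: Bonferroni-corrected two-sided
Wilcoxon signed-rank tests (exact signed-rank distribution for n ≤ 25
without ties, normal approximation with continuity and tie corrections
otherwise; paired by sentence), and the Quade blocked rank test with Conover
pairwise post-hoc comparisons (within-block ranks weighted by range ranks;
F-distributed omnibus, t-distributed pairwise statistics; a fully tied design
returns p = 1 rather than 0/0). Both are validated against permutation and
enumeration oracles in the test suite, and the Quade omnibus is additionally
cross-checked against `stats::quade.test`.

## The synthetic-data generator

The generator produces a reference corpus and a patient corpus of the same
sentences with known ground truth. Design choices, and what they do and do
not emulate:

* **Latent articulation** is band-limited Gaussian noise (spectral shaping
  toward low frequencies, then an 8 Hz low-pass; unit variance), gated by a
  raised-cosine speech envelope with 0.5 s silence margins — matching the
  annotation convention of keeping 500 ms of silence around speech — and
  0.2 s ramps. It has the statistical structure of articulator motion
  (smooth, band-limited, correlated with the acoustics) but no phonetic
  content.
* **Acoustics**: mel = a fixed one-hidden-layer tanh map of the articulation
  (so the articulatory-to-acoustic network has something genuinely nonlinear
  to learn), with $c_0$ tracking articulatory energy so silence is quiet;
  F0 = a smooth 80–300 Hz contour gated by two-state semi-Markov voicing
  with a 100 ms minimum state duration (so the 50 ms segment filter has
  work to do). Waveforms are synthesized by the vocoder back end.
* **The patient corpus** re-utters each sentence along a random strictly
  increasing time warp (strength 0.3 by default, plus a tempo change), with
  a fixed affine speaker shift on the mel features and a pitch-scaled F0 —
  mimicking a different speaker of a different gender.
* **Neural signals** (1000 Hz) encode the patient's articulatory and
  acoustic features so that a linear decoder with the right context window
  can recover them, which is the property every downstream test relies on:
  each electrode carries nine amplitude-modulated carriers spaced 20 Hz
  apart from 35 Hz — the 200 ms Hamming analysis window has its first
  spectral null at 10 Hz, so each carrier sits on its neighbours' nulls and
  its measured band power stays clean — with carrier amplitude equal to the
  square root of a linear function of a lagged latent (so measured *power*
  is linear in the drive), plus a slow 0–8 Hz mixture feeding the 0.5–5 Hz
  feature. Carrier-to-latent assignment is a balanced round-robin; readout
  lags (±50 ms) are balanced across electrodes. Articulation-driven
  electrodes are tagged "frontal", acoustically driven ones "temporal", and
  F0 is present in every temporal electrode's slow mixture, giving the
  region analyses a testable ground truth.
* **Montage realism that keeps referencing benign**: electrodes carry large
  static polarization offsets (half positive, half negative) and two quiet
  strip-like contacts (reference and ground) sit in between, so the
  across-channel median is always a latent-free contact. A shared 50 Hz
  mains artifact is added to every contact; the common median reference
  removes it. Without this construction the sample-wise median of
  same-scale channels is a switching nonlinearity that measurably corrupts
  band-power linearity.
* **Noise**: 1/f-shaped Gaussian noise scaled relative to the signal.
  The default `noise_sd` is calibrated so that direct-decoding median
  correlations land in the 0.4–0.6 range under the standard configuration —
  a convenience for realistic-looking summaries, not a claim about real
  signal-to-noise ratios.

What passing tests on this generator shows: that every pipeline stage is
implemented correctly, leak-free and internally consistent. What it does not
show: performance on real cortical data, where the encoding is nonlinear,
non-stationary and far noisier, and where articulatory transfer inherits all
the imperfections of cross-speaker acoustics.

## Numerical choices and degenerate inputs

* Zero-variance features keep sd = 1 in the z-score state (the column maps
  to constant 0), so feature dimensions are stable across folds.
* Per-sentence Pearson r is defined as 0 (flagged degenerate) when either
  signal is constant.
* DTW ties prefer the diagonal step; the local distance clamps tiny negative
  values arising from floating-point cancellation to 0.
* The Quade test returns p = 1 (flagged) when all treatments are identical.
* Warp generation guards strict monotonicity by flooring the warp slope.
* Seeds: every stochastic stage takes an explicit seed; corpora are
  bit-reproducible, and derived seeds are kept below $2^{31}$.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the pipeline at desk scale,
chosen as the package's own study conditions: recovery runs use 40 sentences
of 3–5 s at 16 signal electrodes, noise-free, with an 80/20 train/test split
(the per-feature recovery criterion is evaluated as the median per-sentence
correlation over held-out sentences); chance-level and noise-calibration
runs use ~20 sentences; the synthesizer checks use reduced hidden layers
(the full 3×512 architecture is the default for real use). The statistical
calibration uses 2,000 null simulations of an 8×3 design. The full
experiment sweeps of the evaluation module (`run_sweep`) reproduce the
study's comparison grids (PCA sizes 10–200, contexts 0–210 ms, delays ±200
ms, PLS components 3–100) and are sized to run in minutes on one CPU at
these corpus sizes.

## Known limitations

* The vocoder is analysis-consistent but not perceptually tuned; no
  aperiodicity/mixed excitation, so breathy or creaky voice quality is out
  of scope.
* The F0 tracker is a plain autocorrelation estimator; it is pluggable by
  design, and any 80–300 Hz-constrained estimator can replace it.
* The L-curve ridge variant over-regularizes when data are nearly noise-free
  (a known property of the L-curve criterion); the cross-validated variants
  are preferable in that regime.
* The synthetic neural encoding is engineered to be linearly decodable;
  real electrocorticography offers no such guarantee, and absolute
  correlation values obtained here do not transfer to real data.
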