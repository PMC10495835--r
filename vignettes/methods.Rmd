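---
title: "Decoding sequential finger movements from EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding sequential finger movements from EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A sequential finger-movement paradigm encodes a brain-computer-interface
command in *two* keystrokes rather than one: the left or right index finger
presses a key, and the same or the other finger presses again about one
second later, giving four task classes (LL, RR, LR, RL). Two complementary
EEG signatures distinguish the classes:

* the **movement-related cortical potential (MRCP)** — a slow (< 3 Hz)
  negativity over sensorimotor cortex that ramps up before each keystroke
  and is stronger over the hemisphere *contralateral* to the moving finger
  (left finger → right hemisphere, C4; right finger → C3);
* **event-related desynchronization (ERD)** — a drop of alpha (8–13 Hz)
  and beta (13–30 Hz) rhythm power around each keystroke, again with
  contralateral dominance.

This package implements the full analysis: a synthetic-data generator that
reproduces the paradigm's statistical structure, preprocessing, MRCP and
ERSP characterisation, a spatial-filter feature bank (DCPM, TRCA, FBCSP),
mutual-information feature selection and linear-SVM decoding, offline
(cross-validated) and online (blocks 1–6 train, blocks 7–8 test).

## The synthetic-data generator

No public recordings accompany the paradigm, so every stage is exercised on
synthetic EEG whose construction mirrors the protocol: 60 channels on the
10–20 montage, 1,000 Hz native sampling (tests and the acceptance run use
250 Hz; see *Problem sizes*), a nose reference, 50 Hz line interference.
The offline schedule is 10 blocks × 60 trials with each task occurring 15
times per block in seeded random order; the online schedule is 6 such
blocks plus two 40-trial feedback blocks (20 LL + 20 RR, then
20 LR + 20 RL). Each trial has a 1 s ready cue, a self-paced first
keystroke (uniform 1.2–2.0 s after the cue — below 1.2 s the widest
analysis window would clip the cue period), a second keystroke
1.0 s ± jitter later, and 2 s rest.

Per trial the generator renders, deterministically given the keystroke
times:

* an MRCP per keystroke: a linear negative ramp starting 1.5 s before the
  press, peaking at the press (default −8 µV), and returning to baseline
  along a half-cosine over 0.5 s. The spatial profile is a Gaussian kernel
  (distance decay 0.35 in montage units) centred on the contralateral hand
  area (C4 for a left press, C3 for a right press) plus the mirrored
  kernel down-weighted by the contralateral ratio (default 2). The second
  press of a *repeated*-finger task is scaled by 0.8, reflecting the
  weaker non-initial negativity of a rehearsed repeat.
* ongoing alpha (10 Hz, 5 µV) and beta (20 Hz, 3 µV) rhythms over the
  sensorimotor region whose amplitude is multiplied by (1 − depth) inside
  a (−0.5, 0.5) s window around each keystroke, contralaterally weighted;
  default depths 0.5 (alpha) and 0.4 (beta).
* spatially mixed 1/f background noise (20 pink sources plus sensor
  noise, 6 µV), 50 Hz line interference (2 µV), and optional frontal
  blink artifacts (2/min, 100 µV at the forehead).

Keystroke times are snapped to the sample grid and the rhythms are
phase-locked to each trial's first keystroke, so that with noise, line and
blinks disabled and zero jitter the average epoch of a task equals its
class template to machine precision — the generator's strongest self-check.

**What this emulates and what it does not.** The generator reproduces the
*spatio-temporal mean structure* the analyses rely on (contralateral MRCP
ramps, band-limited ERD, 1/f background, line noise, blinks, behavioural
violations) but not several properties of real EEG: rhythms are sinusoidal
and phase-locked rather than stochastic narrowband processes, there is no
trial-to-trial amplitude variability or non-stationarity across blocks, no
volume-conduction-realistic mixing, and no inter-subject variability beyond
the seed. Synthetic decoding accuracies are therefore *optimistic*
(near-ceiling at default SNR) and passing tests demonstrate correctness of
the pipeline, not expected performance on real recordings. Default
amplitudes were chosen once as plausible round values at which the full
pipeline clearly exceeds chance.

## Preprocessing

* **Notch**: second-order IIR notch (biquad), default Q = 30 — the design
  is unspecified in the source description, so a standard, parsimonious
  one is used — applied zero-phase.
* **Butterworth filtering**: "4th-order zero-phase" is read the standard
  EEG way: a 4th-order design applied forward–backward, doubling the
  magnitude order and cancelling phase. A "0–3 Hz" low-pass is a 3 Hz
  low-pass (a 0 Hz corner is undefined). Edges are padded with
  odd-symmetric reflection before filtering.
* **Resampling**: zero-phase anti-alias low-pass at 45% of the target
  rate, then interpolation onto the target grid. Event indices rescale by
  `target/rate` with round-half-away-from-zero (a symmetric, documented
  tie-break).
* **CAR**: the instantaneous channel mean is subtracted, so the channel
  mean is exactly zero at every sample.
* **Trial rejection** drops a trial iff its key codes contradict the
  task's finger sequence, its keystrokes are more than 2 s apart, or it
  lacks exactly two key events; every drop carries a reason.
* **ICA artifact removal** is an automated, reproducible stand-in for
  manual component inspection: FastICA (symmetric orthogonalisation,
  logcosh contrast) on a PCA-reduced subspace, with components removed
  when their source correlates with an EOG reference beyond a threshold
  (default 0.8). It is optional and off by default in the acceptance runs,
  because the simulated blinks barely load the sensorimotor channels and
  the stage's seed-dependence would otherwise propagate.

The pipeline order is: notch → (optional ICA) → branch-specific filtering
and resampling. Feature-branch filters are applied to the *continuous*
signal before epoching so filter transients stay away from the short
feature windows.

## MRCP and ERSP characterisation

MRCP: resample to 16 Hz → 3 Hz low-pass → CAR → epochs [−2, 3) s around
the first keystroke (80 samples; all epoch windows are half-open
`[tmin, tmax)` so sample counts are unambiguous across the 16/200/1,000 Hz
rates). Grand averages are computed subjects-first when a subject
partition is given (subject means are the statistical units), and the
pointwise paired t-test between two conditions is two-sided with no
multiple-comparison correction across time points (raw p < 0.05 shading is
the convention being reproduced; a Bonferroni option exists). Zero-variance
time points are flagged degenerate and reported at p = 1. Topographies
read the waveform at the grid point nearest −150 ms and 850 ms, reporting
the snapped time.

ERSP: resample to 200 Hz → CAR → 4–30 Hz band-pass → epochs wide enough
for a 256-sample Hanning STFT around [−1.5, 2.5] s. Frames advance by 64
samples (25% hop); trial-averaged *power* is converted to dB
(10·log10) and then linearly interpolated onto a 0.1 s reporting grid —
averaging power before the dB conversion is the standard ERSP order, and
the alternative (dB then average) was considered and rejected because it
estimates a different (geometric-mean) quantity. The per-frequency mean
over the (−1.5, −1.0) s baseline is subtracted:
`ERSP = ERSP_original − ERSP_baseline`, so negative values are ERD. The
frequency grid is forced by the window: bins of 200/256 = 0.78125 Hz,
restricted to 4–30 Hz. Raw-power output is available behind `db = FALSE`.

## The feature bank

Feature epochs are [−0.5, 1.5) s at 200 Hz (400 samples), anchored to the
*first* keystroke only — one window per trial covering both presses at
their ~1 s spacing. The per-keystroke alternative (two overlapping windows
per trial) was considered; a single anchored window is used because the
trial is the classification unit and the second keystroke's latency jitter
would blur a second-anchor template. Branches: 1–8 Hz (MRCP branch, for
DCPM and TRCA) and 4–8 / 8–13 / 13–30 Hz (filter bank, for CSP).

All three methods reduce to symmetric-definite generalized eigenproblems,
solved by Cholesky whitening with eigenvector signs fixed so the
largest-magnitude coefficient is positive (deterministic across
platforms). All covariance/scatter estimates receive scalar shrinkage
toward a scaled identity (default intensity 0.05 — 60 channels against a
few hundred trials makes unregularized estimates ill-conditioned; a fixed
small intensity keeps the fits deterministic and is exposed as a
parameter).

* **DCPM** (discriminative canonical pattern matching), one-vs-rest per
  class: DSP filters maximize between-class over within-class spatial
  scatter; the top 2 dimensions project the class mean into a template.
  At transform time an epoch yields, per class and dimension, the plain
  Pearson correlation with the template and the corresponding canonical
  correlation after CCA alignment — 4 classes × 2 dims × 2 similarities
  = **16 features**. The internal composition of the published 16 is not
  derivable from its total; this layout is the minimal construction
  consistent with 4 classes and 2 DSP dimensions and is recorded as an
  assumption.
* **TRCA** (task-related component analysis), per class: filters maximize
  inter-trial covariance over total covariance; the top 3 components
  project trials and the class template, whose concatenated-component
  Pearson correlation is the class score — **4 features**.
* **FBCSP**, per band and class one-vs-rest: CSP eigenproblem
  `C_class v = λ (C_class + C_rest) v` on trial-averaged,
  trace-normalized covariances, keeping the top 3 filters; features are
  block-normalized log variance shares — 3 bands × 4 classes × 3 filters
  = **36 features** (one-vs-rest, not pairwise, is what makes the count
  36 rather than 54).

Concatenation gives the 56-wide per-trial feature vector
[16 DCPM | 4 TRCA | 36 FBCSP] with stable names.

## Decoding

Mutual information between each feature and the labels is estimated from a
10-bin equal-width histogram over the feature's training-set range (a
simple, deterministic, oracle-testable estimator; no estimator is
prescribed by the source description). Ranking ties break by ascending
feature index. The top k features (k = 10 online; swept by nested
cross-validation over {5, 15, …, 55} offline, because *that* a selection
occurred is stated but not *how*) are z-scored with training statistics
and fed to a linear SVM with C = 1 (libsvm via e1071 — the same library
family as the original implementation; multiclass is one-vs-one voting).
Offline evaluation is stratified 10-fold cross-validation with seeded
shuffling at the trial level (block-level stratification is unstated in
the source; trial-level is implemented and documented);
`pipeline_crossvalidate()` refits the spatial filters inside every fold so
no stage sees a test trial. The online simulation fits everything once on
blocks 1–6 and classifies block 7 (LL-vs-RR) and block 8 (LR-vs-RL).

## Numerical choices and degenerate inputs

* Half-open epoch windows `[tmin, tmax)`; epoch length
  `round((tmax − tmin) · rate)`.
* Event samples are 0-based (sample 0 = t 0) in all tables and files.
* Resampling event tie-break: round half away from zero.
* Constant features get MI 0; zero-variance paired differences get p = 1
  with a degenerate flag; zero-variance CSP projections raise an error
  naming the band.
* Rank-deficient scatter matrices raise an error instructing shrinkage
  when the shrinkage intensity is 0.
* EDF output quantises to the 16-bit digital range and the 8-character
  physical-range header fields; the writer scales with the *truncated*
  header values so a round-trip is exact to writer precision.

## Problem sizes

Unit tests run on a reduced 18-channel montage and 1–2 blocks of trials at
250 Hz; the acceptance checks run the full 600-trial offline protocol and
the full 440-trial online protocol on the 60-channel montage at 250 Hz —
sizes chosen as the smallest that exercise every protocol count while the
spectral content (≤ 30 Hz analysis band, 50 Hz line) stays far below
Nyquist. The native 1,000 Hz rate changes only the resampling ratios.

## Known limitations

* Synthetic rhythms are phase-locked to the keystroke; real alpha/beta is
  not, so DCPM/TRCA templates capture more information here than they
  would on real data.
* The ICA stage estimates at most `n_components` sources and flags them by
  correlation with a single EOG reference; overlapping artifact sources
  (saccades vs blinks) are not separated.
* The 16-feature DCPM layout reproduces the published feature *count*,
  not necessarily the original feature values.
* No inter-subject transfer, no real-time streaming, no figure rendering
  (tables are the export surface).
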