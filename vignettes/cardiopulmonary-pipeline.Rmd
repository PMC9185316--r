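---
title: "Cardiopulmonary sound classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiopulmonary sound classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpsound)
```

## The problem and the model

Auscultation classifies heart and lung sounds as healthy or pathological.
The difficulty is that the *normal* component — the repeating S1/S2 valve
transients of the cardiac cycle, or the breath envelope — dominates the
recording (typically more than 80% of its energy), while the diagnostic
content (murmurs between S1 and S2, expiratory wheezes, crackles) is a
small additive component. `cpsound` implements a pipeline built around that
observation:

1. band-filter the recording to the physiological band (heart < 400 Hz;
   lung 100–2000 Hz);
2. cut it into overlapping fixed-length frames;
3. within each frame, remove the dominant periodic structure with PCA and
   keep the residual;
4. summarise each residual with 27 features;
5. classify frames with a boosted/bagged tree ensemble and vote the frame
   calls into a sample-level decision across a 5%–95% threshold grid.

The pipeline assumes (a) the normal template repeats several times per
frame, so it is low-rank in a sub-window embedding; (b) abnormalities are
aperiodic or spectrally distinct, so they survive into the residual; and
(c) a sample's abnormality is expressed in *some* fraction of its frames,
not necessarily all of them — hence voting instead of frame-majority
pooling only.

## Segmentation

Frames of length $F$ seconds are taken every $H = F(1-\rho)$ seconds for
overlap ratio $\rho$, so a signal of $L$ seconds yields
$\lfloor (L-F)/H\rfloor + 1$ frames; trailing partial frames are dropped
(padding would dilute the frame statistics with silence). The supported
grids — $F \in \{1, 1.5, 2\}$ s for heart, $\{3, 4, 5\}$ s for lung,
$\rho \in \{0, 0.2, 0.5\}$ — cover one full cardiac cycle at 50–80 bpm and
one full breath at 12–20 breaths/min. A sample yielding fewer than two
frames is *excluded* and reported (`excluded_ids`), never silently
classified from a single frame; excluded samples do not enter fold counts.
Frame start times are quantized to whole samples with round-half-even,
which matters only for rates where $H \cdot \text{rate}$ is not integral.

## The PCA residual

The embedding question — how a 1-D frame becomes a PCA-able matrix — is
genuinely open, and we chose the simplest option whose low-rank part
captures a repeating template: the frame is reshaped row-wise into
`n_subwindows` (default 20) consecutive equal sub-windows; any trailing
remainder shorter than one sub-window is carried into the residual
unmodified. With 2 s heart frames, 20 rows give 100 ms sub-windows —
shorter than a cardiac cycle, so the cycle repeats across rows. An
alternative reading (PCA across the frames of one sample, frames as
observations) is plausible but couples frames together and would leak
sample-level structure across fold boundaries; the within-frame embedding
keeps frames independent.

Columns are mean-centred; the SVD gives variance fractions
$d_i^2/\sum_j d_j^2$; the smallest $k$ whose cumulative contribution
reaches the threshold (default **0.95**, configurable in $[0.85, 0.95]$)
is reconstructed and subtracted. Numerical conventions:

* an all-constant (zero-variance) frame returns an all-zero residual with
  `removed_fraction = 1`;
* the threshold comparison uses a $10^{-12}$ slack so exact ties (e.g.
  four equal fractions of 0.25 against 1.0) resolve deterministically;
* the residual satisfies, to machine precision, the energy split
  (centred variance = removed + residual) and orthogonality between the
  residual and the removed reconstruction — both are tested identities.

## The 27 features

Eleven statistics, thirteen cepstral values, three spectral summaries.
Estimator choices the feature names alone do not pin down:

* **Quartiles** by linear interpolation (R's type-7 default), sample SD.
* **Skewness**: adjusted Fisher–Pearson; **kurtosis**: Pearson (normal
  = 3); both defined as 0 for zero-variance frames.
* **Shannon entropy**: 16 equal-width amplitude bins over the frame's
  range, base-2 log, 0 for constant frames. Sixteen bins on frames of
  thousands of samples keeps the estimator's bias modest while remaining
  sensitive to heavy-tailed residuals (crackles).
* **Spectral entropy**: normalized by $\log_2(\text{bins})$ so it lies in
  $[0,1]$ and is comparable across frame lengths (≈ 0 for a pure tone,
  > 0.9 for white noise).
* **MFCC**: pre-emphasis 0.97; 25 ms Hamming sub-windows, 10 ms hop; FFT
  length `max(256, next pow2(window))` — the floor guarantees every one of
  the 40 Mel filters (2595·log10(1 + f/700) scale, 0 to rate/2) spans at
  least one FFT bin, without which floored log-energies would break the
  amplitude-scaling invariance of coefficients 1–12; orthonormal DCT-II;
  coefficients 1–12 averaged across sub-windows; 13th value = log total
  frame energy floored at $10^{-12}$. MFCC is computed on the residual
  (the difference signal), as is the whole feature block.
* **Power spectrum**: raw (untapered) periodogram of the whole frame, so
  line components fall into single bins; features are the peak power, its
  frequency, and its fraction of total power.

A note on dimensions: a 2 s frame at 2000 Hz has 4000 samples, reduced to
27 features. (Printed figures of ~240,000 points per 2 s frame circulate
for this pipeline; they are inconsistent with the stated rate, and the
package uses true frame lengths throughout.)

## Ensembles

All five methods are implemented over a shared weak-learner interface.
Depth-1 base learners are *exhaustive* decision stumps — every split of
every feature scanned for minimum weighted misclassification error
(classification) or weighted SSE (regression) — so the first AdaBoost round
provably coincides with the optimal stump; depth ≥ 2 trees delegate to
`rpart` with cost-complexity pruning disabled. GentleBoost and LogitBoost
follow their standard additive-logistic-regression formulations (Newton
steps on the exponential/binomial loss); RUSBoost is AdaBoost where each
round's learner is fit on all minority-class frames plus an equal-sized
uniform draw of majority frames, with weight updates on the full set.
Scores are additive; the frame decision threshold is fixed at score 0 —
class imbalance is addressed by RUSBoost's resampling, not by shifting the
decision point.

`select_model()` reproduces the randomized selection procedure: each of 5
trials draws a method at random and tunes (ensemble size ∈ [50, 500],
depth ∈ [1, 4], learning rate ∈ [0.01, 1]) by Bayesian optimization — a
Gaussian-process surrogate (squared-exponential kernel, length-scale 0.3
on the unit cube) with expected-improvement acquisition over 20
evaluations, the first third from a Latin-hypercube design. The objective
is mean stratified 3-fold accuracy on the training frames; accuracy (not
F1) is the tuning objective, a choice left open by the procedure's
description, and both the budget and objective are arguments.
`kfold_evaluate()` defaults to a fixed AdaBoost configuration (100 stumps,
learning rate 1) rather than `"auto"`: on separable synthetic corpora the
selection machinery adds cost but not accuracy, and a fixed default keeps
evaluation runs light; `classifier = list(method = "auto")` enables the
full procedure.

## Voting and evaluation

A sample is abnormal when its abnormal-frame fraction **strictly exceeds**
the threshold — "exceeds" is read literally, so a fraction exactly at the
threshold votes normal; the sweep uses the 19-point grid 5%, 10%, …, 95%.
Metrics follow the confusion-count definitions (accuracy, specificity,
sensitivity, precision, F1), with zero denominators mapped to 0 and F1
defined as 0 when sensitivity + precision = 0. Folds are stratified at the
*sample* level (frames never straddle folds), dealing each class
round-robin with a fold counter continued across classes so per-class
counts stay within one of proportional *and* fold sizes within one of
$n/k$; plain random splitting is fragile under the strong class imbalance
typical of heart-sound corpora. The final report averages per-fold metrics
(unweighted) per threshold, rather than pooling counts; fold counts
default to 5 (heart) and 3 (lung).

## The synthetic generator

The generator produces the statistical structure the classifier assumes,
not physiologically faithful waveforms:

* **Heart** (2000 Hz, matching common heart-sound corpora): S1 as a
  Gaussian-windowed 40 Hz tone (~60 ms) at each cycle start, S2 at 60 Hz
  (~40 ms) at 35% of the cycle; heart rate uniform in 50–80 bpm; an
  abnormal recording adds band-limited (default 150–400 Hz) noise bursts
  filling systole, amplitude `murmur_amp`; white noise floor 0.002;
  peak-normalized to 0.9.
* **Lung** (8000 Hz, so the 2000 Hz band edge is resolvable): broadband
  100–2000 Hz noise under one $\sin^2$ envelope per breath (12–20/min);
  wheezes add a tone during the expiratory half; crackles add ~6 ms damped
  650 Hz transients at seeded random times.
* **Noise mixtures**: ward-construction and airport noise stand-ins are
  white noise band-passed to 150–450 Hz and 100–600 Hz (the bands such
  sources occupy in measurement); the reference channel is the same
  process under a gain/delay/frequency-shift coupling, the last emulating
  the medium-dependent pitch shift that degrades two-channel subtraction.

Default corpus durations are 10–15 s (heart) and 15–25 s (lung) — desk-
scale values inside the 5–120 s and 10–90 s ranges of the public corpora
this emulates. Everything is deterministic given the spec seed, and labels
are exact functions of the abnormality parameters.

What passing tests on this generator do **not** show: robustness to real
murmur morphology (ejection vs regurgitant spectra), disease subtypes,
recording-device variation, or the label noise of clinical corpora.
Synthetic separability is high — the end-to-end check (60 recordings,
30/30, murmur amplitude 0.5, 2 s frames, 20% overlap, 20% voting
threshold, stratified 5-fold) demands accuracy ≥ 0.90 and typically
reaches 1.0. That validates the pipeline's plumbing and its monotone
threshold behaviour, not clinical performance; headline numbers on the
public heart/lung corpora require those external downloads and are out of
scope here.

## Known limitations

* The WAV layer reads PCM int 8/16/24/32 and float 32/64 only; exotic
  RIFF variants (ADPCM, WAVE_FORMAT_EXTENSIBLE beyond PCM/float) are
  rejected with a format error.
* The heart filter is the 400 Hz design value; heart sounds extend lower
  and (weakly) higher, and no attempt is made to reconcile the wider
  1–800 Hz physiological range with the 400 Hz design band.
* `pca_residual()`'s sub-window embedding is one of several defensible
  readings of "PCA on the frame"; it is isolated behind one function so a
  cross-frame variant can be swapped in.
* The Bayesian optimizer is a deliberately small GP-EI implementation
  (fixed kernel, random candidate maximization); it is a tuning aid, not a
  general-purpose optimizer.
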