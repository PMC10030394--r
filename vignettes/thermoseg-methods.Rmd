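---
title: "Methods: per-pixel tumor segmentation from cold-stress thermal video"
author: "thermoseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-pixel tumor segmentation from cold-stress thermal video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the measurement

During open brain surgery the exposed cortex can be imaged passively with a
thermal-infrared camera. Tumor tissue differs from healthy parenchyma in
perfusion and metabolism, which leaves traces in the surface temperature
field — both in its resting fluctuations and in how the tissue re-warms
after a standardized perturbation (irrigation with cold saline). thermoseg
implements a complete per-pixel analysis of such recordings: the protocol
is one minute of baseline (BL), a cold-saline injection, and two minutes of
recovery (REC), sampled at 5 Hz. Every pixel of the thermal video becomes a
feature vector, and a per-patient classifier separates tumor from healthy
pixels, using a surgeon-drawn boundary (transferred from a visible-light
image by affine co-registration) as the label source.

Because clinical recordings of this kind are not publicly available, the
package ships a synthetic-video generator that reproduces the statistical
structure the pipeline relies on; all tests and the acceptance analyses run
on it. What that does and does not demonstrate is discussed at the end.

## Co-registration

The tumor boundary is drawn on a visible-light image. Given at least three
non-collinear landmark pairs, `estimate_affine()` solves the ordinary
least-squares problem `min sum_i ||A s_i + t - d_i||^2` for the 2-D affine
map; with exactly three pairs the fit is exact. RANSAC-style robust fitting
is deliberately not used: landmarks are operator-chosen and few, so every
pair is trusted. `transfer_boundary()` maps the polygon vertices and
rasterizes them with an even-odd rule on pixel centers (0-based (row, col)
coordinates, centers at integers; pixel centers on the boundary count as
inside — a deterministic convention pinned by the test oracles). File I/O
converts to the 1-based (x, y) convention of common imaging tools at the
boundary only.

## Time-domain features

For each pixel the package computes, per phase window:

* **Exponential recovery fit** `y = a (1 - exp(b x)) + c` over the REC
  trace, `x` in seconds from recovery onset: `a` (deg C) is the asymptotic
  re-warming amplitude, `b` (1/s, negative) the inverse time constant, `c`
  (deg C) the post-stress starting temperature. The fit is kept only when
  the goodness of fit `R = sqrt(max(R^2, 0))` exceeds 0.8 strictly;
  otherwise the pixel's fit features are missing (imputation happens in the
  classifier, explicitly). `R` is the correlation form of the coefficient
  of determination; for least squares with an intercept-bearing model it
  equals the Pearson correlation of observed and fitted values.
* **Temperature variation** `delta`: mean of the last 10 s minus mean of
  the first 10 s of the whole recording (positive = net warming). Windows
  are time-based, `[t0, t0+10)` and `(t_end-10, t_end]` with `t_end` the
  exclusive end of sampling.
* **Initial temperature** `t_ini`: mean over the 30 s before the injection.
* **Moments** per window: sample SD, kurtosis (non-excess; a Gaussian
  gives 3, matching the Matlab convention most of this literature uses),
  skewness, and the 90th percentile with type-7 linear interpolation.
* **Sample entropy** `SampEn(m, r, N) = -ln(U^{m+1}/U^m)` with `m = 2` and
  `r = 0.2 SD`, where `U^k` counts distinct template pairs of length `k`
  matching within Chebyshev distance `<= r` (closed tolerance,
  self-matches excluded, identical normalization in numerator and
  denominator so it cancels). Constant windows return 0 and are flagged;
  `U^{m+1} = 0` returns `+Inf`. The implementation is exact
  pair counting in C++, and the tests hold it to exact agreement with an
  independent R oracle.

### Fitting strategy

The recovery model is linear in `(a, c)` once `b` is fixed, so the fit uses
variable projection: the profile residual sum of squares is evaluated on a
fixed 80-point log-spaced grid of `b` in `[-2, -5e-4]` (time constants of
0.5 s to 2000 s), each evaluation a closed-form linear solve vectorized
across all pixels, and the best grid cell is refined by golden-section
search. This is deterministic, needs no starting values, cannot diverge,
and fits 4096 pixels in a few seconds. Flat traces (`a = 0`, `b`
unidentifiable) have zero total sum of squares, undefined `R`, and are
rejected — the gate doubles as the identifiability check.

## Frequency-domain features

The frequency-domain representation of a pixel is its wavelet coherence
against a reference trace: the mean time course of a random 20% subset of
tumor pixels (`make_reference()`, seeded). Coherence is computed with an
analytic Morlet continuous wavelet transform (centre frequency parameter
6, the standard choice in the coherence literature) on 60 bands whose
edges are log-spaced over [0.015, 2] Hz — log spacing because wavelet
scale resolution is multiplicative; linear spacing is available for
sensitivity checks. The magnitude-squared coherence is

    C = |S(Wx conj(Wy))|^2 / (S(|Wx|^2) S(|Wy|^2))

with a smoothing operator `S` that is a boxcar over time of span three
wavelet scales plus a three-point boxcar across scales — the minimal
standard smoothing that makes coherence non-trivial (< 1). Values are
clipped to [0, 1]; self-coherence is exactly 1; the estimator floor for
independent white noise averages about 0.4 with this smoothing, and the
tests require it below 0.5.

Choices worth knowing:

* One transform of the full trace is windowed into BL and REC afterwards,
  rather than transforming the phases separately, so the phase boundary
  adds no extra edge effects. The smoothing span still mixes information
  across the boundary at scales comparable to the window length; that is
  inherent to time-frequency analysis at these durations.
* Samples inside the cone of influence (sqrt(2) x scale from either edge)
  are excluded from band averages. On the 60 s BL window the five lowest
  bands have no usable samples at all; they are reported as `NaN` and the
  classifier drops them with a warning. Bands whose window is shorter than
  one period of the band's lower edge are flagged unreliable by
  `band_average()` but still reported.
* "Coherence amplitude" is implemented as magnitude-squared coherence, the
  standard definition.
* Reference-subset pixels stay in the feature table, flagged in
  `in_reference`; `thermoseg(exclude_reference = TRUE)` removes them from
  training for circularity-sensitive analyses. The default keeps them,
  with the flag making either analysis reproducible.

## Feature screening

`test_features()` applies a two-sample Welch t-test per feature (pooled
variance available by flag; the unequal-variance default is the safer
choice for per-pixel features whose dispersions differ by class) with
Bonferroni correction over the features of the table at family-wise 0.05.
The orientation of `t` is explicit — class 0 minus class 1 or the reverse.
`max_discriminative_band()` averages per-band t-values across patients and
returns the argmax band, breaking ties toward the lower frequency.

## Classification

Per patient, labeled pixels are split 20% train / 20% test / 60%
validation uniformly at random; train and test are balanced separately by
randomly down-sampling the larger class (the removed pixels join no set
and are recorded). An RBF-kernel SVM (`e1071`, C = 1, gamma = 1/p on
standardized features — equivalent to the common "scale" heuristic once
features are z-scored) is trained on the balanced training set, with four
feature families: time-domain or coherence features, from BL only or from
BL+REC. Standardization and train-median imputation of missing fit
coefficients are fit on the training rows only and stored with the model.

Reported metrics are the validation-set accuracy, sensitivity and
specificity (percent; tumor = positive class). Ten-fold cross-validation
runs over the balanced train+test pool — the only reading of a "20/20/60
split plus 10-fold CV" protocol that leaves the validation set untouched —
with imputation and standardization refit inside every fold; fold-level
accuracies and their mean and SD are reported alongside. The
cross-validation estimates generalization on balanced data, while the
validation metrics reflect the true class imbalance; both are kept because
they answer different questions.

## The synthetic scenario

`simulate_thermal_video()` generates, per pixel: a constant baseline level
(Gaussian across pixels), a step drop at the injection instant, an
exponential re-warming whose clock starts at recovery onset (the 10 s
post-injection transient holds at the dropped level and is excluded from
every feature window; the real injection duration is not standardized, so
the transient length is a configuration knob), a narrowband cardiac
oscillation, a shared slow global drift, and white sensor noise. The
cardiac component of a pixel is `w * shared + (1 - w) * own`, where the
shared and per-pixel sources are unit-variance Gaussian noise band-passed
around the cardiac frequency: the mixing weight `w` is the knob that makes
tumor pixels (default `w = 0.9`) coherent with a tumor-derived reference
and healthy pixels (default `w = 0.1`) not. A band-limited stochastic
source rather than a drifting sinusoid is essential here: independent
constant-frequency sinusoids hold a locally stable phase over any
smoothing window and would look fully coherent regardless of `w`.

Default conditions (all configurable):

| quantity | healthy | tumor | why |
|---|---|---|---|
| baseline mean | 33.5 degC | 32.7 degC | tumors run 0.5-2 degC cooler |
| baseline spatial SD | 1.0 degC | 1.0 degC | clinical per-area SDs ~0.5-2 |
| cold-stress drop | 3.5 degC | 4.5 degC | tumor reacts more, stays perturbed |
| recovery amplitude a | 3.3 degC | 4.2 degC | each regains most of its drop |
| recovery tau (-1/b) | 35 s | 80 s | tumor re-warms ~2x slower |
| cardiac frequency | 0.71 Hz | 0.71 Hz | centre of the discriminative band |
| cardiac amplitude | 0.03 degC | 0.03 degC | perfusion-driven pulsation scale |
| coherence weight w | 0.1 | 0.9 | the class contrast the FD features use |
| parameter heterogeneity | 30% | 30% | tumors and perfusion are heterogeneous |

with sensor noise SD 0.05 degC (camera NETD scale), cardiac bandwidth
0.15 Hz, shared drift SD 0.3 degC below ~0.05 Hz, 64 x 64 frames, and a
12-vertex elliptical lesion covering ~12% of the frame. Three of these
choices deserve their reasoning spelled out:

* **Both classes keep re-warming through the whole 2-minute recovery
  window** (tau of 35 s and 80 s). If the healthy class saturates early,
  its late-recovery slow-frequency content is pure noise and decoheres
  from the tumor-mean reference, and the lowest coherence bands become
  implausibly discriminative — the measured temperature of a cold-stressed
  cortex is still climbing at the end of a 2-minute window, and the window
  length only makes sense if it is.
* **Tumor has the larger excursion** (deeper drop, larger regain). With
  both classes ramping all window, the recovery-window SD is governed
  mainly by the excursion amplitude, and the tumor-higher-dispersion
  pattern requires the tumor to move more — consistent with reading tumor
  tissue as reacting more strongly and staying perturbed longer.
* **30% within-class heterogeneity** of the recovery parameters. With
  near-identical pixels per class, per-pixel coherence features become
  deterministic to three decimals and t-statistics explode on microscopic
  mean differences; realistic heterogeneity restores finite-variance
  statistics.

The shared global drift (identical in every pixel, hence adding no class
contrast by construction) represents ambient and irrigation-driven slow
temperature changes of the exposed cortex; it anchors the low-frequency
coherence of all pixels.

What the generator does **not** emulate: spatial correlation of the
baseline field (off by default so pixels are exchangeable and the split
protocol's independence assumptions hold), tissue motion and brain shift,
vascular-tree geometry, radiometric camera effects, and any spatial
structure within the lesion. Passing tests on this generator therefore
demonstrate that the pipeline's mathematics and bookkeeping are correct
and that its discriminative logic works when the assumed class contrasts
are present — not that those contrasts have the assumed form in real
recordings.

## Numerical and degenerate-input policy

* Recovery fits: rejection (never an exception) for flat traces,
  non-identifiable parameters, or sub-threshold R; batched grid +
  golden-section refinement is deterministic to ~1e-8 in `b`.
* Coherence: zero-power traces yield `NaN` coherence, flagged; every
  finite value clipped to [0, 1]; COI exclusion everywhere.
* Sample entropy: `0` (flagged) for constant traces, `+Inf` when no
  `(m+1)`-template pair matches.
* Splits: an error (suggesting a reseed) if a class is absent from the
  train or test pool; balancing never touches the validation set.
* TIFF storage quantizes temperatures to 32-bit samples over a recorded
  range (~1e-8 degC steps); the writer returns the quantized video so
  round trips are exactly reproducible.
* All stochastic steps (generator, reference subset, splits, CV folds)
  take explicit seeds; a cohort run is byte-reproducible from its
  configuration.

## Problem sizes

The bundled analyses use 64 x 64-pixel videos (4096 pixels, 950 frames)
and 5-patient cohorts; unit tests use 16 x 16 desk-scale scenarios with a
shortened protocol. These sizes were chosen so a full cohort — simulation,
both feature domains, four classifier families with cross-validation —
completes in a few minutes on one CPU while keeping per-class pixel counts
in the thousands, where the per-pixel statistics are stable. Full-size
(640 x 480) generation is supported by the same code paths.

## Known limitations

* The per-pixel independence of the generator understates the optimism of
  random pixel splits on spatially correlated real data; on real
  recordings, spatially blocked splits would be the stricter protocol.
* The BL-window coherence at sub-0.05 Hz bands rests on very few samples
  outside the cone of influence; those features are reported but carry
  little information and are dropped from classifiers when all-missing.
* Wavelet coherence at scales comparable to the recording length mixes
  baseline and recovery information through the smoothing operator; the
  windowing bounds, not eliminates, this.
* The SVM hyperparameters are fixed defaults (C = 1, gamma = 1/p); a small
  in-training-set grid search is available but off by default, since the
  synthetic contrasts are far from the margin where tuning matters.
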