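---
title: "Methods: lesion detection on synthetic breast-MRI phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion detection on synthetic breast-MRI phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the models it implements, the
assumptions behind them, the parameters that matter, and the design choices
made where the method family leaves the design open. The numbers quoted in
the README are produced by `scripts/acceptance.R` and the test suite; this
document states no result that those do not themselves compute.

## The pipeline at a glance

`run_pipeline()` chains six stages: adaptive Kalman denoising, lesion
segmentation by a small pyramid-pooling network trained with the jellyfish
search optimizer, geometric augmentation of the training split, a
five-family feature bank, a compact classifier trained with an
error-similarity-weighted cross-entropy loss, and confusion-matrix metrics.
Every stage derives its seed from the single `config$seed` by fixed offsets,
so stages are independently reproducible.

## The phantom: what it emulates and what it does not

`phantom_spec()` defines the study conditions. Each slice is a smooth
anatomical background — Gaussian-blurred white noise (sigma 6 px) rescaled
to `[40, 160]` on a 0–255 intensity scale — plus, for malignant samples, one
filled elliptical lesion with random center, orientation, and semi-axes
drawn from 8–20 % of the image side. The lesion sits 60 intensity units
above the local background (a 20-unit base offset plus the 40-unit
`class_contrast`) and carries a sinusoidal texture (amplitude 20,
0.35 cycles/pixel for malignant; 0.15 for the optional benign lesion).
Additive Gaussian noise (sigma 10) is applied last; a Rician option takes
the magnitude of the signal plus a complex Gaussian pair, the standard model
of MRI magnitude noise. Benign samples are lesion-free by default,
mirroring the sick/healthy structure of clinical MRI screening collections;
`benign_lesion = TRUE` adds a low-contrast benign lesion instead.

These choices give every feature family genuine signal: intensity (offset),
texture (frequency), shape (mask geometry) and histogram statistics. What
the phantom deliberately does **not** emulate: 3-D anatomy, bias fields,
dynamic contrast-enhancement time curves, multiple or non-elliptical
lesions, and scanner-specific artifacts. Passing tests on phantoms
therefore demonstrate that the pipeline's machinery is correct and that its
stages compose, not that its accuracy transfers to clinical images.

## Adaptive Kalman denoising

Each image row is treated as a scalar time series: the state is the true
intensity, modeled as a random walk with process variance `q`; the
measurement is the observed pixel. The filter re-estimates the
measurement-noise variance at every pixel as the mean of the last
`window = 15` squared innovations minus the predicted state variance,
clamped from below (`1e-6`) because the raw estimate can go negative. The
default is bidirectional: forward and backward sweeps are averaged, which
cancels first-order directional lag. Initialization is `x0 =` first pixel
of the line and `P0 =` global image variance; the innovation window warms
up with however many innovations exist.

The one consequential tunable is `q` (intensity² per pixel step, default
**200**). Small `q` assumes a nearly static scanline: the filter then
smooths aggressively, and because the innovation-based adaptation treats
pixels inconsistent with the model as noise, a 10–25-pixel lesion is
flattened almost entirely — good global MSE, useless input for
segmentation. At `q = 200` the filter retains most of the lesion contrast
(the test suite asserts at least 60 % survives) while still cutting the
noise MSE substantially at noise sigma 20 (the acceptance script reports
the measured MSE ratio). This is
the classic bias–variance trade of structure-preserving denoising, and the
default sits deliberately on the structure-preserving side.

## Segmentation: pyramid pooling at desk scale

The segmenter is a deliberately small pyramid-pooling network: a 3x3
convolutional encoder (affine batch norm, ReLU; 2x average pooling between
stages when there are several), adaptive average pooling of the encoder
output at several bin counts, a 1x1 reduction + ReLU per branch, bilinear
upsampling, concatenation with the pre-pooling features, and a 1x1
convolution + sigmoid head. Batch normalization is an affine scale and
shift only: a population-based trainer has no minibatch-statistics
protocol, so running moments would be ill-defined. Inputs are min-max
normalized per image, which places lesion intensities at a consistent
position of `[0, 1]` whatever the slice's brightness range.

All parameters form one flat vector (77 for the `tiny` preset) optimized by
jellyfish search over `[-2, 2]` against the mean per-pixel squared error
between the probability map and the ground-truth mask. Two presets are
provided; `tiny` (single 4-channel stage, pyramid bins {1, 2}, 32-px input)
is small enough for a 30x300 jellyfish budget to train reliably. A
parameter cap (5000) refuses architectures a derivative-free search cannot
fit. Probability maps are thresholded at 0.5 (`>=` convention).

The Dice benchmark in the tests trains on the 8 lesion-bearing phantoms of
the default-seed dataset — one trains a lesion segmenter on images that
contain lesions; lesion-free benign slices contribute nothing to the
mask-regression objective and, at these sample sizes, dilute it.

## Jellyfish search

The optimizer maintains a population of candidate vectors initialized by a
logistic chaotic map (parameter 4, degenerate starts rejected) and mapped
affinely into the box. Per iteration and per jellyfish, a time-control
draw `|(1 - t/N)(2r - 1)|` decides the move: at or above 0.5, an
ocean-current step toward the incumbent best (`best - eta r1 * mean`,
scaled by a fresh draw); below, a swarm move — passive (a `chi r (U - L)`
exploration step) with probability equal to the decaying time-control
value, else active (a step along the direction to a random neighbor,
toward it if the neighbor is better, away otherwise). Positions are
hard-clipped to the box. Candidates replace their jellyfish only when they
improve it (greedy acceptance), and the incumbent best is tracked
separately, so the best-so-far curve is non-increasing and equals the
minimum over all evaluations.

Two scheme details deserve a note because the method family leaves them
open and they decide whether the optimizer works at all. First, the swarm
branch must become *more* exploitative over time: passive probability equal
to the decaying time-control value (the canonical scheme). Inverting it —
passive probability growing with time — lets the positively-biased passive
step keep kicking converged jellyfish away from the optimum. Second, greedy
acceptance matters: with unconditional moves the sphere benchmark stalls
many orders of magnitude short of the tolerance the test suite asserts;
with greedy acceptance it converges far below it (the acceptance script
reports the median sphere fitness it reaches).

## Augmentation

Rotation about the image center (right angles by exact index permutation,
arbitrary angles by bilinear resampling with nearest-neighbor masks and
zero fill), the three exact flips (row reversal, column reversal, both —
the last identical to a 180° rotation), and random erasing of one square
patch (side a random fraction of the image side, fully inside the frame).
Erasing alters the image only, never the mask: it models occlusion of
appearance, not anatomy. Geometric operators transform image and mask
identically; labels always survive. Augmentation happens after the
train/test split, training side only, so no augmented copy of a held-out
image can leak into training.

## The feature bank

Five families, concatenated in a fixed documented order
(`5 stats x (16 Gabor + 1 LBP + 4 LVP maps) + 4 shape = 109` values):

* **Gabor magnitudes** at frequencies {0.1, 0.2, 0.3, 0.4} cycles/pixel and
  orientations {0, 45, 90, 135}°, complex kernels under an envelope that
  scales with wavelength, reflect padding, FFT correlation.
* **Local binary patterns**: 8-bit codes, neighbors starting East and
  proceeding counter-clockwise, ties (`>= 0`) counting as 1, borders 0.
* **Local vector patterns**: first-order directional derivatives at
  {0, 45, 90, 135}° compared through the comparative-space ratio transform
  (slope guarded to 0 where the reference derivative vanishes), radius 1,
  8 neighbors, 2-pixel borders 0.
* **Shape** of the segmentation mask's largest connected component:
  compactness `P/A` with a crack-edge perimeter, eccentricity as the
  moment-ellipse axis ratio (pixels treated as unit squares, so a w x h
  rectangle scores exactly w/h), rectangularity `A / eccentricity`, and
  solidity `A / convex area` with the hull taken over pixel corners so a
  filled rectangle scores exactly 1. An empty mask yields zero shape
  features at the pipeline level (there is no region to describe);
  `shape_features()` itself refuses empty masks.
* **Histogram statistics** per texture map over 256 levels: mean, variance,
  SD, and skewness/kurtosis normalized by powers of the **mean** — an
  unconventional normalization kept deliberately as part of this feature
  bank's definition (the usual convention divides by powers of the SD).
  Maps already within `[0, 255]` are binned by rounding so integer code
  maps have exact histograms; other maps are min-max scaled first. Both
  are defined as 0 when the mean is 0. A consequence of the mean-power
  normalization is occasional extreme values on near-degenerate maps; the
  classifier clips standardized features at ±8 SD for this reason.

## Classifier and the error-similarity loss

The classifier is dual-input: the 109-vector through a one-hidden-layer
dense branch (standardized, clipped, ReLU), and optionally the stacked
feature image (intensity, LBP, 4 LVP, mean Gabor) through a two-stage conv
+ pool stack with global average pooling. Branches concatenate into a
softmax output layer. The default pipeline uses the dense branch only; the
conv branch is exercised by the unit tests and available by configuration.

The loss is cross-entropy scaled by the gap between the largest predicted
probability and the true-class probability,
`-(t_max - t_eps) log t_eps`, with the weight treated as a detached
constant so the analytic gradient is exactly
`(t_max - t_eps)(t - onehot)`. Confidently correct samples contribute
nothing; ambiguous and wrong samples dominate. Two structural consequences
are worth knowing. First, the loss is *zero-margin*: once `t_eps = t_max`
the gradient vanishes, so training converges to separators with no margin
and a few boundary samples hover at probability ~0.5 — training accuracy
on separable toy data plateaus near, but not at, 1. Second, the loss has a
degenerate stationary set at uniform probabilities; finite learning rates
and the interior layers' plain-SGD updates move through it, but
update-starved schedules can park there.

Interior layers take plain gradient steps per minibatch. The output layer
follows a CAViaR-style lagged recursion per training iteration: ratios of
the current to the two lagged errors (clamped to `[0, 10]`, a zero lagged
error giving the maximal ratio), normalized to sum to one, blend the two
lagged weight matrices and their gradients. The recursion as printed in
its source family defines the update implicitly and leaves its driving
function unspecified; this package's forward reading — convex blend of
lags, driven by lagged gradients, degrading to plain SGD until two errors
are recorded — is stable by construction (the blend is convex) and reduces
exactly to SGD when the lags coincide. The raw unnormalized variant and a
plain-SGD ablation are both available by configuration.

## Evaluation

Accuracy, sensitivity and specificity come from the confusion counts, with
errors (not NaN) on empty denominators. `kfold_evaluate()` runs seeded,
stratified K folds, augments training folds only, and reports per-fold and
mean ± SD metrics. Leave-one-out folds hold a single class, so only
accuracy is defined there.

## Problem sizes and numerical choices

The package's reference experiments are sized for a laptop-class single
CPU: 64-px phantoms, 200 train / 100 test for the end-to-end experiment,
8 training images at 32 px with a 30x300 jellyfish budget for the
segmenter benchmark, 100 Monte-Carlo draws for the denoising check. The
FFT correlation pads reflectively to image-plus-kernel size; bilinear
resampling uses the half-pixel center convention so constant images are
exact fixed points; the logistic initializer rejects the map's degenerate
points; probability maps use the `>=` threshold convention; prediction
ties break toward the lower class index. Intensities are floating point
end to end and quantized only on file write (8- or 16-bit).

## Known limitations

* The phantom's simplicity means reported end-to-end numbers characterize
  the implementation, not clinical performance.
* The segmenter is desk-scale by design; a derivative-free population
  search does not scale to deep backbones (the parameter cap enforces
  this honestly).
* The error-similarity loss's zero-margin property (above) caps attainable
  training accuracy slightly below 1 on clean separable data.
* The adaptive Kalman filter is one-dimensional per scanline; it is a
  denoiser, not an anisotropic edge-preserving smoother, and its `q`
  default trades some noise suppression for structure preservation.
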