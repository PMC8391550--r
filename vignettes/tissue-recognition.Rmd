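---
title: "Hyperspectral tissue recognition: models, metrics and the synthetic cohort"
author: "hsinerve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperspectral tissue recognition: models, metrics and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsinerve)
```

## The problem

Nerves are thin, low-contrast structures that are easy to injure during
surgery because they are hard to see. Hyperspectral imaging (HSI) records a
full absorption spectrum at every pixel — here 100 equally spaced bands from
500 nm (visible green) to 1000 nm (near infrared) — so that tissue types
with indistinguishable RGB appearance can still differ spectrally. This
package implements a per-pixel recognition pipeline for seven classes found
in an open neck dissection: artery, fat, metal (retractor), muscle, nerve,
skin and vein, coded 1–7 in alphabetical order (0 marks unlabeled pixels).

For every pixel of interest, a 5 × 5 × 100 sub-volume centered on the pixel
is extracted and passed to a predictive model that emits one score per
class; the pixel is assigned to the arg-max class, with exact ties broken
toward the lowest class code. Two model families are compared, each with
and without standard normal variate (SNV) spectral normalization — four
configurations: CNN, CNN+SNV, SVM, SVM+SNV.

## The 3D CNN

The network is a compact 3D CNN: six convolutional hidden layers that
down-sample mainly along the spectral axis, one fully connected hidden
layer, and a 7-neuron linear output. The input is treated as a one-channel
volume with 100 spectral planes of 5 × 5 pixels:

| layer | kernel (depth × h × w) | stride / dilation (depth) | output (C × D × S) |
|---|---|---|---|
| conv 1 | 3 × 3 × 3, pad 1 | 1 / 1 | 22 × 100 × 3×3 |
| conv 2 (down) | 3 × 1 × 1 | 2 / 3 | 22 × 48 × 3×3 |
| conv 3 | 3 × 3 × 3, pad 1 | 1 / 1 | 31 × 48 × 1×1 |
| conv 4 (down) | 3 × 1 × 1 | 2 / 3 | 31 × 22 × 1 |
| conv 5 | 3 × 1 × 1, pad 1 | 1 / 3 | 31 × 18 × 1 |
| conv 6 (down) | 2 × 1 × 1 | 2 / 2 | 31 × 9 × 1 |
| fully connected | 279 → 15 | | 15 |
| output | 15 → 7 | | 7 scores |

All hidden layers are ReLU. With this configuration the network has exactly
**32,628 trainable parameters** (asserted in the test suite and recomputed
by `scripts/acceptance.R`). The kernel/stride/dilation sequence follows the
established down-sampling 3D-CNN design for spectral volumes; the channel
widths (22, 31) and the 15-unit hidden layer are the unique variant of that
sequence matching the target parameter count for a 5 × 5 × 100 input and 7
classes.

```{r params}
model <- buildCNN()
countParameters(model)
```

Training minimizes a class-weighted softmax cross-entropy, with weights
inversely proportional to the per-class training counts and normalized to
sum to the number of classes (any positive scaling is loss-equivalent up to
the learning rate; one convention is fixed). Optimization is Adam at
learning rate 0.001. Epochs (12), minibatch size (32) and the uniform
fan-in initialization are not prescribed by the problem and are package
defaults: batch 32 gives enough optimizer steps to reach the held-out
accuracy plateau on cohorts of the default size within seconds per fold,
and 12 epochs is where that plateau is reached. All of it is seeded and
configurable.

Two implementations of the network exist and are cross-checked in the test
suite: a pure-R double-precision reference (used for gradient checking
against numerical differentiation) and compiled single-precision kernels
(`engine = "single"`, the default) that express each convolution as a
precomputed gather plus one BLAS product. Training is deterministic given
the seed: the minibatch order is drawn from R's RNG and the kernels are
single-threaded.

## The SVM baseline

The baseline is a support vector machine with a radial-basis kernel at
C = 1 (the customary library default; a "degree" setting is meaningless for
an RBF kernel and is ignored). Its feature space has exactly 100
dimensions: the relative absorption of each wavelength at the *center
pixel* of the sub-volume. The spatial window therefore carries no
information on the SVM path — spatial context is precisely what the CNN
adds. (The alternative reading, averaging the window per band, was
rejected: window averaging mixes thin structures and region borders into
neighboring classes, which breaks the separability limit discussed below.)
Features are auto-scaled per band (mean 0, variance 1) with the scaler
fitted on the training fold only and stored inside the model, so inference
cannot bypass it. Multi-class classification uses the one-vs-one scheme;
per-class scores for ROC analysis are the summed signed pairwise decision
values. The SVM is not class-weighted, matching default-parameter usage.

## SNV normalization

SNV transforms each pixel's curve to zero mean and unit standard deviation.
It removes exactly the positive-affine family `a * x + b` (illumination
gain and offset caused by surface orientation and distance), at the price
of discarding absolute-level information. A constant curve has no shape to
preserve: it is an error, never a silent division. Models record the
normalization they were trained with and reject inputs whose provenance
tag differs — preprocessing symmetry is enforced, not trusted.

## Leave-one-patient-out cross-validation

With `n` subjects there are `n` folds; fold `i` trains on all subjects
except `i` and tests on subject `i`, so performance measures generalization
to unseen subjects, the clinically relevant question. Everything fitted —
SNV flag aside (it is per-pixel and parameter-free), the band scaler, the
class weights and the model — sees training subjects only; the driver
asserts structurally that the held-out subject never enters training.

Metrics per fold and pooled: confusion matrices row-normalized so each row
sums to 1 (rows with zero support are flagged, never divided; the diagonal
equals per-class sensitivity); one-vs-all sensitivity, specificity and
Sørensen–Dice coefficient (DSC = 2TP/(2TP+FP+FN), the harmonic mean of
precision and sensitivity); ROC curves per class with trapezoidal AUC —
equal, with ties counted one half, to the probability that a random
positive outscores a random negative, an identity the tests verify against
a brute-force pairwise oracle; and two-tailed paired t-tests across folds
between configurations, starred at p < 0.05 and p < 0.01. Per-class means
are reported with both standard deviation and standard error across folds
(conventions differ between tabular and graphical reporting; both are
available). Classes absent from a subject's annotations are excluded from
that fold's per-class mean, not scored zero. ROC scores are pooled over all
folds' test pixels rather than averaged per fold; with one curve per class
and model, pooling matches "all pixels in the test images" most directly.

## The synthetic cohort

No in vivo acquisition is distributed with the package, so a scene
generator provides annotated cohorts with the statistical structure that
matters for the method, each subject a 64 × 64 × 100 cube (a desk-scale
stand-in for the camera's 640 × 476 frame; full size is supported):

* **Geometry.** A skin background; a central muscle block inside a
  subcutaneous-fat margin; artery and vein tubes (3 px) flanking a 1-px
  nerve — a neurovascular bundle; a metal retractor bar. Nerves are the
  thinnest structures by construction.
* **Spectra.** Smooth per-class mean absorption curves (sums of Gaussian
  bumps over 500–1000 nm) constrained by the ordinal relations of real
  tissue spectra: muscle, nerve and fat are mutually the closest pairs
  (`nerveMuscleSimilarity`, default 0.8, morphs the nerve mean toward the
  muscle mean); vein and skin have the largest mean distance to the other
  tissues; metal is flat and dark. The curves are package defaults, not
  measurements.
* **Variability.** Per pixel: a lognormal gain and Gaussian offset (the
  affine family SNV removes — the generator and SNV are exact duals, a
  property the tests exploit), a smooth band-correlated deviation, and
  independent band noise. Per subject: a smooth spectral shift, 90 %
  shared across tissues (common illumination and physiology) and 10 %
  tissue-specific. Metal additionally produces saturating specular spikes
  with probability 0.15, giving it the largest total variance of any class.
* **Partial volume.** A fixed 3 × 3 point-spread blur (weights 0.4 / 0.1 /
  0.05) is applied per band. This is the decisive realism ingredient for
  the nerve problem: a 1-px nerve retains only ~60 % of its own signal,
  the rest leaking in from surrounding muscle, so nerve pixels are
  intrinsically the hardest class for every model, while interior muscle
  pixels stay pure. A center-pixel model (the SVM) sees only the diluted
  spectrum; a windowed model (the CNN) can additionally exploit the
  spatial line pattern.
* **Annotation.** Sparse and conservative: region cores are eroded (2
  passes where the region is thick enough; thin structures keep their full
  region) and subsampled per class, producing severe imbalance with skin
  the most and nerve among the least represented classes.

The cohort is a pure function of (configuration, seed): one global seed
derives per-subject streams, and the whole pipeline — including CNN
training — is deterministic given the seed, so identical runs produce
byte-identical metric bundles.

### What the dials show

Two properties connect the generator to the method's claims and are
exercised by the test suite at the stated problem sizes:

* **Separability dial.** With every variability scale at zero
  (`scaleVariability(models, 0)`, subject effect 0, blur off) and the
  confusability dial at zero, every pixel is exactly its class's distinct
  mean curve, and all four configurations reach per-class sensitivity
  ≥ 0.99 under LOPOCV on an 8-subject cohort — a pipeline smoke test
  showing that residual error at default difficulty comes from the modeled
  variability and confusability, not from the machinery.
* **Confusability dial.** At default difficulty, run over three seeds and
  averaged, nerve is the lowest-sensitivity class for every configuration,
  and the CNN's nerve sensitivity exceeds the SVM's. This is a qualitative,
  directional replication; no numeric agreement with any in vivo result is
  claimed. The SNV ablation is genuinely two-sided in this generator: SNV
  removes the gain/offset nuisance (helping the variance-limited SVM on
  nerve) but discards absolute-level information.

What the generator does **not** emulate: real chromophore physics
(hemoglobin, water, lipid absorption are only cartooned), breathing or
motion artifacts, spatially varying illumination fields, annotation errors,
and inter-patient anatomical variation beyond spectral shifts and geometry
jitter. Passing tests therefore demonstrate the correctness and the
qualitative behavior of the pipeline, not clinical performance.

## Numerical choices and degenerate inputs

* Cubes are stored on disk as 32-bit-float band-sequential ENVI pairs with
  lowercase header keys; reading a written cube reproduces it exactly at
  that precision.
* Coordinates are 1-based (row, column), band axis last, matching R
  indexing conventions; annotated pixels enumerate in row-major order.
* Sub-volume extraction at image borders uses edge replication; interior
  extractions reproduce the raw cube block exactly.
* Constant spectra (SNV) and zero-variance bands (auto-scaling) are errors
  naming the offending pixel or band — the generator never produces them,
  so silence would mask bugs.
* The compiled training path computes in single precision; scores differ
  from the double-precision reference at the 1e-3 level, which is far below
  any decision margin the tests rely on.
* Significance stars use per-comparison alpha (0.05, 0.01) with no
  multiple-testing correction; p-values are reported to 4 decimals.

## Problem sizes used by the test suite

Unit tests run on 40 × 40 scenes with 2–3 subjects. The pipeline-level
properties use the default 64 × 64, 8-subject cohort (roughly 200 annotated pixels
per subject, 1,400 training sub-volumes per fold), 12 training epochs at
batch 32 for the CNN — sizes at which a full four-configuration LOPOCV
comparison completes in minutes on one core while leaving the qualitative
structure of the problem intact.

## Limitations

The architecture is fixed to the 5 × 5 × 100 input geometry family (any
window ≥ 5 and band count compatible with the down-sampling arithmetic
works; the 32,628-parameter count is specific to the default). No data
augmentation, drop-out, transfer learning or hyperparameter search is
implemented. The SVM's ROC scores derive from one-vs-one decision values,
which are comparable across pixels but are not calibrated probabilities.
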