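---
title: "Detecting cardiovascular landmarks and classifying HLHS anatomy from axial cine stacks"
author: "landmarknet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cardiovascular landmarks and classifying HLHS anatomy from axial cine stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landmarknet)
```

## The problem

Hypoplastic left heart syndrome (HLHS) after Fontan palliation produces a
cardiovascular geometry that differs drastically from normal anatomy: the
native aortic valve is replaced functionally by the neo-aortic (former
pulmonary) valve, the ventricular arrangement changes, and the great
vessels are rerouted.  `landmarknet` implements a two-stage pipeline that
exploits this: a convolutional network detects seven anatomical landmarks
in an axial cine MRI stack, and a linear support vector machine (SVM)
classifies the *spatial arrangement* of those landmarks — never the image
itself — as HLHS or normal anatomy.  Decoupling detection from
classification keeps the decision transparent: the classifier can only use
clinically meaningful geometry, not scanner- or protocol-specific image
features.

The seven landmarks, in their fixed numbering, are: (1) origin of the left
common carotid artery, (2) aortic isthmus, (3) tricuspid valve,
(4) aortic / neo-aortic valve, (5) mitral valve, (6) right ventricular
apex, (7) descending aorta at diaphragm level.

## Pre-processing

Axial SSFP stacks arrive with 17–54 slices, 5–8 mm slice spacing and
in-plane resolutions between 1.2 and 2.3 mm.  `preprocessStack()` maps any
such stack to a canonical 33 × 256 × 256 volume:

* slices beyond number 33 (counted from the top of the stack; below the
  diaphragm in practice) are discarded, and stacks with fewer than 33
  slices are zero-padded at the bottom;
* every slice is resampled in-plane to 256 × 256 with bilinear
  interpolation, anisotropically if the acquisition matrix was non-square,
  and the per-axis voxel spacings (and origin) are rescaled so that voxel
  indices keep addressing the same millimetre positions.

The interpolation scheme and the handling of anisotropic matrices are
choices of this package (the preprocessing contract only fixes the output
shape); bilinear resampling was chosen because it is smooth, cheap, exactly
the identity when the input is already 256 × 256, and idempotent on
canonical stacks.  Voxel indices are 0-based, a voxel's position is its
centre, and axes are ordered (z = slice, y = row, x = column); in
millimetre space these correspond to the foot–head, anterior–posterior and
right–left directions.

## Heatmap regression

Rather than regressing coordinates directly, each landmark j is encoded as
a Gaussian *heatmap* on the network's output grid:

$$ t(v) = k \exp\left(-\sum_d \frac{(v_d - p_d)^2}{2\sigma_d^2}\right) $$

with peak temperature $k = 10^3$ at the landmark voxel $p$ and
$\sigma_d$ equal to one voxel extent per axis, i.e. the exponent is
$-\sum_d \Delta_d^2/2$ in index units.  The large $k$ keeps early-epoch
mean-squared-error gradients strong; the one-voxel $\sigma$ makes the
target sharply peaked yet differentiable.  Reading $\sigma$ in index units
rather than millimetres makes the construction dimensionless and
resolution-adaptive (on isotropic grids the two readings coincide).

Heads emit volumes of 33 × 64 × 64 — the in-plane resolution is a factor
4 below the input.  Targets are therefore generated directly on the coarse
grid: in-plane annotation indices are divided by 4 and rounded, slice
indices are kept.  When a prediction is mapped back, the coarse in-plane
index c becomes the centre of its fine block, $4c + 1.5$, before
conversion to millimetres.

The predicted landmark is the argmax voxel of the predicted heatmap.  If
the maximum is attained at several voxels, the tie is broken by the
7 × 7 × 7 neighbourhood sum $S$ around each candidate (window clipped at
the volume edge — equivalent to zero padding for non-negative heatmaps,
but explicit); any residual tie falls back to the lexicographically
smallest (slice, row, col) index so extraction is fully deterministic.
Sub-voxel refinement (e.g. a centre-of-mass around the peak) is
deliberately not performed.

## Network architecture

`buildModel()` constructs a U-net-like 3D convolutional network with a
shared encoder backbone and seven decoder heads, one per landmark:

* all convolutions use 3 × 3 × 3 kernels (a package choice; only strides
  and filter counts are architectural constraints), zero ('same') padding,
  ReLU activations and He initialisation; the final convolution of each
  head is linear;
* the encoder halves the in-plane resolution per downsampling step with
  stride 1 × 2 × 2 convolutions — the slice axis is never strided — up to
  depth 7 for the full-size input (256 → 2), and the filter count grows
  additively by 4 per step: 6, 10, 14, … with the default 6 first-layer
  filters;
* a non-strided convolution sits between consecutive resampling steps, and
  same-size encoder feature maps are concatenated into the decoder via
  skip connexions;
* decoder levels at depths above the head-split depth (default 3) are
  shared; the levels at depths 3, 2, 1 are replicated in each of the seven
  heads, so every head owns its last three upsampling steps
  ("splitting into segmentation heads above depth 3");
* each head upsamples back to 256 × 256, applies in-plane max pooling by
  4 and a linear 1-filter convolution, yielding one 33 × 64 × 64 heatmap.

Within a decoder level the order is: transpose convolution (implemented as
zero-stuffing followed by a stride-1 convolution), skip concatenation,
non-strided convolution.  Max pooling precedes the final linear
convolution.  Both orderings are documented choices where the architecture
description leaves them open.

Training minimises the unweighted mean over the seven heads of the
per-voxel MSE with Adam (learning rate 5 × 10⁻⁴, batch size 2, 32 epochs
for the full-size configuration).  All randomness — weight initialisation
and epoch shuffling — flows from explicit seeds, so training runs are
bit-reproducible on a fixed machine.

The engine itself (im2col + BLAS GEMM convolutions, transpose convolution
by zero-stuffing, pooling with argmax bookkeeping, Adam) is implemented in
C++ inside the package; gradients are verified against finite differences
in the test suite.

### Image augmentation

`augmentPair()` reproduces the usual cine-stack augmentation family:
random in-plane shift (≤ 2 % of the image size), rotation (≤ 4°), scaling
(± 15 %), applied identically to every slice and to the landmark
coordinates; blur (kernel radius ≤ 4 px) and a mild radial distortion act
on intensities only.  A transformed landmark leaving the field of view
flags the pair as invalid so it can be skipped.  Augmentation is off by
default: the final detection model is trained without it, the
configuration exists to make the search space reproducible.

## Point clouds and classification

Detected (or annotated) voxel positions are converted to millimetres,
assembled into a 7-point cloud $l_{ji}$, and centred at the landmark
centroid $m_i = \sum_j l_{ji}/7$, giving $L_{ji} = l_{ji} - m_i$.
Centring makes the downstream classification invariant to global
translation of the heart within the scanner — the only standardisation
applied, since all 21 coordinates already share millimetre units.

The classifier is a soft-margin linear SVM (cost 1, the library default)
on the 21 centred coordinates in landmark-major order (L1z, L1y, L1x,
L2z, …, L7x — an ordering this package fixes so weight reports are
well-defined).  `weightSummary()` reports per landmark the signed maximum
and the root mean square of its three coefficients; the landmark with the
largest RMS is the one the classifier leans on most — for HLHS-vs-normal
geometry this is expected to be the aortic/neo-aortic valve, the landmark
that physically moves between the classes.

Optionally the training clouds can be augmented (`augmentPointClouds()`):
each cloud is kept once and added again `nCopies = 400` times with
independent uniform jitter in ± 10 mm per landmark and coordinate
(replicas are re-centred so they remain valid centred clouds).

A decision value of exactly zero is classified as the second class level,
following the strict-inequality convention of the underlying libsvm
implementation.

## Evaluation metrics

* **Displacement** $E = \lVert g - l \rVert$ in mm between annotated and
  predicted positions; `cohortLandmarkStats()` reports per-landmark mean
  and SD over subjects, averaged over cross-validation folds when fold
  labels are given.  Two summaries are deliberately reported side by side:
  the mean *Euclidean* displacement, and the per-component *signed* mean
  (the systematic shift along each spatial direction) — published tables
  of this kind mix the two readings, so both are exposed and labelled.
* **Interobserver variability** $E_{inter}$: the same statistic between
  two observers' annotations, and the ratio of network error to
  interobserver variability as a reference scale.
* **Bland–Altman** per spatial component: bias, SD, 95 % limits of
  agreement (bias ± 1.96 SD — the multiplier is a package choice), and
  the proportional-bias slope from regressing differences on pairwise
  means.
* **Accuracy**: fraction of correct classifications.

Cross-validation is stratified k-fold: subjects are shuffled within each
class and dealt round-robin to folds, which guarantees disjoint validation
folds covering the cohort exactly once with per-fold class counts within
one subject of the cohort proportion.  The default is k = 5 (79 subjects
split 63–64 train / 15–16 validation); k is exposed as a parameter because
published descriptions of this design are not always consistent about the
fold count (five in the methods, four in some table captions), and the
harness should not silently pick for the user.  Within `runCrossval()`
the detection network is retrained from scratch with fresh weights per
fold; the SVM is trained on the *annotated* training clouds and evaluated
on the *detected* validation clouds (or annotated ones with
`useAnnotations = TRUE`, the upper-bound configuration).

## The phantom generator

Real cine stacks cannot ship with a package, so `sampleCohort()` renders
a fully synthetic cohort whose geometry mirrors the study design:

* two classes (46 patients / 33 controls by default) whose 7 landmark
  positions are drawn from class-conditional Gaussian distributions:
  a control template at fixed fractional positions of the field of view
  (superior-to-inferior ordering and the central mediastinal clustering of
  the real structures are kept: the three valve landmarks sit close
  together near the volume centre, the carotid origin high, the
  diaphragm-level aorta low),
  and a patient template shifted by 40 mm at the aortic-valve landmark
  plus mild shifts (10 mm, 8 mm) at the tricuspid valve and apex —
  qualitatively the class geometry reported for real cohorts, where the
  valve landmark separates the classes and should dominate the classifier
  weights;
* within-class jitter SD 3 mm per coordinate — the scale of interobserver
  annotation variability on such data;
* each landmark is rendered as a bright Gaussian blob (σ = half the
  10 mm render radius) with per-landmark amplitudes spaced geometrically
  (0.4 × 1.45^(j−1)), so heads can disambiguate landmarks by appearance
  as well as position, mimicking distinct anatomy (valves, vessels, apex)
  without modelling it; a Gaussian-cross-section tube through landmarks
  1–2–7 adds vessel-like context, and Gaussian background noise
  (SD 0.05, ~8 % of the dimmest blob) is added everywhere;
* the ground-truth annotation is the jittered position quantised to its
  voxel; a simulated second observer re-jitters the truth in millimetres
  (SD 5 mm by default) and re-quantises.

All randomness derives from the single spec seed through per-subject
sub-seeds, so any subject is regenerable in isolation.  What the phantom
deliberately does *not* emulate: anatomical shape variability beyond
landmark positions, bSSFP contrast and banding, cine temporal dynamics,
intensity inhomogeneity, and observer biases that correlate across
landmarks.  Tests passing on phantoms therefore demonstrate that the
pipeline's machinery — preprocessing, heatmap encoding/decoding, network
training, centring, classification, metrics — is correct and learnable,
not that the network reaches clinical accuracy on patient data.

## Desk-scale configurations

The full-size network (33 × 256 × 256 input, depth 7, 6 first-layer
filters) is built and exercised for shape contracts, but training it is a
GPU-scale task.  For CPU-scale end-to-end runs the package uses a reduced
configuration chosen once and used throughout tests and the acceptance
script: 33 × 64 × 64 phantoms on a 2 mm / 6 mm grid, `maxDepth = 3`,
`headSplitDepth = 2`, 3 first-layer filters, batch size 1, 10 epochs, and
a learning rate of 0.02 — the largest rate at which training is stable
from a cold He-initialised start (larger rates diverge in the first epoch
and leave decoder units dead).  The higher rate partly compensates for
having roughly an order of magnitude fewer optimiser steps than the
full-size recipe.  Problem sizes in the tests (8–16 training subjects,
4–8 held-out) were chosen so the whole suite runs in minutes on one CPU
while still giving the classifier enough subjects per class in every
fold.

An important property of this few-step regime deserves emphasis: with
only ~100–300 Adam steps, convergence is not uniform across the seven
decoder heads.  Individual heads can remain under-converged — in the
extreme, emitting a near-constant temperature field whose argmax is
essentially arbitrary — depending on the weight initialisation and the
cohort draw, while the remaining heads recover their landmarks to within
grid quantisation (a single-subject overfitting probe drives most heads
to exact voxel recovery with peak temperatures near k).  The end-to-end
test therefore measures and reports the achieved held-out displacement,
but a blob-radius-level mean displacement is not guaranteed at this step
budget; reliable convergence of all seven heads is observed to need
several times more optimiser steps than a 10-epoch desk-scale run
provides, consistent with the full-size recipe's ~10³ steps.

## Numerical choices and degenerate inputs

* Resampling uses centre-aligned bilinear interpolation
  (input coordinate = (output + ½)·zoom − ½); it is exactly the identity
  at zoom 1.
* Heatmap extraction on an all-constant volume returns voxel (0,0,0) by
  the documented lexicographic policy; an all-NaN heatmap is an error.
* `preprocessStack` accepts any positive slice count; appended slices are
  exactly zero.
* Centred clouds must average to zero within 10⁻⁹ mm — this is a class
  invariant, enforced at construction.
* The SVM fit is deterministic for a fixed input order (libsvm with a
  fixed cost and no scaling); "random initial weights" have no effect on
  the converged linear solution beyond solver tolerance.
* Annotations with a slice index beyond the 33-slice crop are rejected
  with a validation error rather than silently moved.

## Known limitations

* DICOM support is a minimal explicit-VR little-endian reader/writer
  (enough for round-tripping phantom series and plain single-frame
  exports); orientation matrices, compressed syntaxes and vendor tags are
  out of scope, as is cine-phase selection — the end-diastolic frame is
  assumed pre-selected.
* The training engine is CPU-bound (convolution arithmetic in single
  precision, everything else double); it is meant for desk-scale
  validation and reduced problem sizes, not for reproducing GPU-scale
  training times, and at desk-scale step budgets the per-head
  convergence variability described above is the dominant detection
  error source.
* The per-head decoder replication means memory grows with the head-split
  depth; the full-size forward pass peaks at roughly 2 GB.
* Hyper-parameter search (first-layer filters 3–9, head depth 2–6) is
  exposed through `modelConfig()` but not automated.
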