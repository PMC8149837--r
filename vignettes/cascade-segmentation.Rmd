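---
title: "Cascade CNN brain tumor segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascade CNN brain tumor segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cascadeseg` segments gliomas in multi-modal brain MRI (FLAIR, T1, T1ce,
T2) into the standard BRATS tissue classes — normal tissue (0), necrosis
(1), edema (2) and enhancing tumor (4) — using three cooperating
components: a rule-based localizer that restricts all later work to a
small "expected area" around the tumor, a deterministic distance-wise
attention (DWA) feature, and a compact two-route cascade convolutional
network that classifies one voxel at a time from paired global and local
patches. This vignette explains each stage, the tunable parameters and
their defaults, the numerical choices made where the design was open,
and what the synthetic phantom experiments do and do not demonstrate.

## Intensity normalization

MRI intensities are not comparable across scanners or sequences, so each
modality of each subject is z-scored independently: subtract the mean
and divide by the (population, ddof = 0) standard deviation computed
over the brain region only, leaving the background at exactly zero. The
brain region is defined as the union of nonzero voxels across the four
modalities, which is exact for BRATS-style skull-stripped volumes with
zeroed background. Population rather than sample variance was chosen so
that the output has unit variance in the literal sense; at brain-region
voxel counts the two differ negligibly. The operation is invariant under
positive affine rescaling of the input and idempotent to floating-point
tolerance, and both properties are tested.

## Rule-based tumor localization

The localizer exploits two observations about gliomas in axial stacks:
the tumor is bright relative to brain tissue in FLAIR and T2 (and its
enhancing rim much brighter in T1ce), and its cross-sectional area
changes smoothly from slice to slice, growing to a maximum and shrinking
again. Per slice:

1. **Binarization.** The z-scored FLAIR, T2 and T1ce slices (T1 is not
   used for localization) are thresholded at 0.7, 0.7 and 0.9. Because
   z-scores are unbounded, the fractional thresholds are applied after
   min–max rescaling each slice's within-brain intensities to [0, 1]; a
   constant (degenerate) slice yields an empty mask. Fractional
   thresholds in (0, 1) could equally act on rescaled z-scores or on
   rescaled raw intensities; rescaled z-scores were chosen and the
   choice is isolated in `binarize_modality()`. Thresholding is strict
   (`>`), so raising a threshold can only remove pixels — a tested
   monotonicity property.
2. **Cleaning.** Each binary slice is opened with a disk structuring
   element of radius 2 and components smaller than 30 px are discarded.
   The opening radius and floor are configurable; they remove
   noise-induced speckle without eroding tumor-scale objects.
3. **Shape rules (T1ce only).** Each remaining T1ce component is kept
   only if solidity > 0.7 AND area > 500 px AND major axis length >
   35 px, all strict inequalities. Solidity is area over filled convex
   hull area (pixel counts); the major axis length is the standard
   ellipse-of-inertia measure, four times the square root of the larger
   eigenvalue of the second central moment matrix of the pixel centers.
   Components are 8-connected.
4. **Fusion.** The cleaned FLAIR and T2 masks are multiplied (logical
   AND); a surviving T1ce object is added only if it overlaps that
   product mask by strictly more than 20 px. Interior holes of the fused
   mask are then filled so the detected parts form one solid object —
   necrotic tissue inside the tumor can fall below the FLAIR/T2
   thresholds, and the search region must not inherit that hole.

**Cross-slice tracking.** A bright object in a single slice may be an
artifact; a true tumor object persists across neighboring slices at
almost the same position and size. Objects in consecutive slices are
linked when their centroids move at most 15 px and their areas change by
at most 50% (relative); a chain at least 3 slices long confirms a true
tumor object. "Same position" and "small size change" fix no numbers by
themselves, so these three tolerances are implementation-defined knobs,
all exposed in `localization_config()`. Among confirmed chains, the one holding the
largest-area object wins, and the biggest object is then re-sought among
all slices' objects within 30 px of the chain's median position, so a
slice just beyond the chain ends (where linking broke because the tumor
tip shrinks quickly) still competes. Area ties resolve to the lowest
slice index, making the whole stage deterministic.

**Expected-area masks.** The biggest object is dilated by 10 px at its
slice; the mask radius then shrinks by 0.5 px per slice away from that
slice, with an accelerated shrink (2 px/slice extra) beyond the
confirmed chain plus a 5-slice margin, until empty. Each slice's mask is
floored at its own tracked object dilated by 3 px, so the detected
object itself is never lost. Rather than iterated erosion, the
implementation thresholds a distance transform of the biggest object's
footprint, which is equivalent for disk structuring elements and much
faster; each nonempty mask is a single connected neighborhood of one
object. The shrink schedule is intentionally much slower than the
phantom tumor's own 2 px/slice decay, buying coverage at the tumor tips
at a modest cost in area. On the default phantoms the masks cover
≥ 99.9% of planted tumor voxels while averaging about 16–18% of the
brain area per slice, consistent with the one-fifth-of-the-image
figure the localization idea is meant to deliver.

## Distance-wise attention

The DWA feature encodes where the expected area sits inside the brain.
For a binary object, the width is the maximum over rows of that row's
true-pixel count and the height is the maximum over columns of that
column's count — run counts, not bounding-box extents; the two differ
for concave objects, and a unit test pins the run-count semantics with
an L-shaped object. The object center is the starting corner plus half
the width/height, kept as floats. For each slice the normalized distance
(Euclidean distance over number of image rows) is computed between the
center of each modality's binary brain silhouette (its nonzero support —
not the tumor-threshold mask) and the center of the expected-area mask,
and the mean over the four modalities is the DWA value of that slice.
A modality with an empty mask on a slice is dropped from the mean; if
all four are empty the value falls back to 1.0, a maximal-prior
sentinel, with a warning. One DWA value per slice is shared by all
samples centered on that slice, and the scalar is appended to the
flattened CNN features just before the classifier head.

## Cascade CNN

Each voxel is classified from two patches centered on it, both with 8
channels (the four raw modalities plus their z-scored versions):

* **Global route** — 40×40 patch through five 3×3 convolutions (ReLU),
  with 2×2 max-pooling after the second and fourth. Default filters
  4-4-8-8-16.
* **Local route** — 15×15 patch through two 3×3 convolutions (ReLU), no
  pooling. Default filters 8-16.

Both routes are flattened and concatenated, the DWA scalar is appended,
dropout at 7% is applied, and a 128-wide ReLU layer feeds a 4-way
softmax. The method fixes the route depths (5 and 2),
the patch sizes, the dropout rate and the four-class softmax, but not
the per-layer filter counts; the defaults here are deliberately compact
so the whole pipeline trains and evaluates in minutes on one CPU core,
and every width is exposed in `model_config()`. Patches may extend past
the image border (zero-padded) and past the expected area — only the
center voxel must lie inside it. For the even 40×40 patch the center
voxel sits at offset `size %/% 2`, a fixed convention.

Training minimizes the softmax cross-entropy
`loss_i = -log(exp(U_p) / sum_d exp(U_d))` with Adam at learning rate
1e-4, weight decay 1e-5 and batch size 2; batch
size 2 is unusually small for patch training and is overridable.
Training patches are drawn class-balanced (an equal per-class quota,
default 100 per subject, without replacement) from inside the expected
area only, which is the method's answer to extreme class imbalance:
lesion and normal-tissue samples are equalized, and drawing background
patches only near the tumor makes them hard negatives. The per-class
count has no canonical value and is a configuration knob. All randomness (initialization, shuffling, dropout)
derives from explicit seeds; a global pipeline seed fans out to
per-stage seeds through a deterministic hash, and retraining with the
same seed reproduces the weights bit for bit.

The network itself is implemented in the package: im2col/col2im and
max-pool kernels in C++ with the matrix products done by R's BLAS, and a
hand-derived backward pass (the analytic softmax-minus-onehot score
gradient is verified against finite differences in the tests).

### Dense inference

Classifying every voxel of a slice by extracting its patch and running
the patch network repeats almost all convolution work between neighbors.
`segment_volume()` therefore evaluates each route densely over the whole
zero-padded slice once and recovers exact per-center features by
bookkeeping: valid convolutions are shift-equivariant, and each 2×2
pooling splits centers into two phases per axis, so after two pooling
stages the global route needs 4×4 = 16 phase variants of its deeper maps
("shift-and-stitch"). Per center, the flattened features reduce to a
small window gather followed by the fully-connected head. The dense
path agrees with the patch path to about 1e-15 (tested) and is purely an
optimization; the patch path is retained as the reference
implementation. Voxels outside the expected area are labeled 0 without
being evaluated, so predicted tumor is a subset of the expected area by
construction.

## Evaluation

Metrics follow the BRATS conventions, computed per region after
binarizing prediction and ground truth by raw-label sets: enhancing
tumor {4}, tumor core {1, 4} (edema excluded), whole tumor {1, 2, 4}.

* **Dice** `2|P∩A| / (|P|+|A|)`; defined as 1 when both masks are empty.
* **Sensitivity** `|P∩A| / |A|`; undefined (NA) for an empty ground
  truth.
* **Hausdorff-percentile distance**: surface voxels are those with a
  6-neighbor outside the mask; the directed nearest-surface distances in
  both directions are pooled and the 99th percentile of the pooled set
  is taken, scaled by voxel spacing in mm — the standard robust
  (HD95-style) construction, at the 99th percentile. Whether the
  reference "HAUSDORFF99" is percentile-based or a robust-max variant is
  not stated; the percentile form was chosen and documented. An empty
  mask yields +Inf with a warning.

## The synthetic phantom generator

Clinical BRATS data are access-restricted, so the package ships a
phantom generator that reproduces exactly the structure the method's
assumptions rest on, making every stage testable offline:

* an elliptical brain (default semi-axes 0.37/0.30/0.55 of the
  240×240×32 default volume) on an exactly-zero background;
* a tumor whose per-slice radius follows
  `r(z) = max(0, r_max − slope·|z − z*|)` (defaults 24 px, 2 px/slice),
  so the per-slice area is unimodal with a known argmax — the tracking
  oracle;
* nested sub-regions: necrotic core within an enhancing rim within
  edema (radius fractions 0.35 and 0.65 of the local radius);
* class-conditional Gaussian intensities on a [0, 1] raw scale chosen
  once to satisfy the assumed contrast orderings (tumor brighter than
  brain in FLAIR/T2; enhancing rim by far the brightest tissue in T1ce;
  necrosis dark in T1ce), with additive noise of SD 0.03;
* an optional single-slice bright blob (default radius 30 px, six
  slices below the peak) — a decoy larger than any single tumor
  cross-section but with no cross-slice support, which tracking must
  reject.

The 240×240 in-plane size matches the clinical volumes; the default
depth of 32 slices keeps desk-scale experiments affordable while leaving
room for the full growth-and-decay profile. Cohorts jitter tumor
position, peak slice and radius per subject under derived seeds; a draw
that would not fit inside the brain is contracted deterministically
toward the base geometry.

What the phantoms do **not** emulate: bias fields, partial-volume
effects, anisotropic voxels, irregular (non-convex, multifocal) tumor
shapes, and inter-subject anatomical variability. Passing phantom tests
therefore demonstrates that the implementation is correct and that the
pipeline's stages compose as designed — not that clinical accuracy
figures transfer. The desk-scale Dice values on phantoms (≈ 0.95 whole
tumor) are much easier than clinical segmentation and should not be
compared with benchmark results.

## Desk-scale experiments and their sizes

The test suite's end-to-end experiment trains the default compact model
on 8 phantom subjects (100 patches per class per subject, 3 epochs) and
segments 2 held-out subjects; it reaches mean whole-tumor Dice well
above 0.85 with predicted tumor confined to the expected area. An
ablation on the same cohort checks two directional claims: appending
the DWA scalar does not materially change phantom accuracy (phantom
tumors are near-concentric, so the feature carries little information
there — the check is that it does not hurt), and removing localization
(training and inferring over whole brain slices with the same budget)
strictly lowers whole-tumor Dice — localization is the component doing
the heavy lifting. `scripts/acceptance.R` re-runs a smaller version (10
localization phantoms; 6 training and 2 test subjects) and writes the
measured quantities as JSON.

## Numerical and degenerate-input choices

* Strict inequalities everywhere a rule says "bigger than"; boundary
  cases (area exactly 500, overlap exactly 20) are excluded, and tests
  pin each boundary.
* Ties for the biggest object resolve to the lowest slice; argmax ties
  in classification resolve to the first (lowest) class index.
* A subject with no confirmed chain raises a localization-failure error
  carrying diagnostics; `run_pipeline()` isolates such subjects (NA
  metric rows) and continues.
* An empty expected area yields an all-background segmentation with a
  warning rather than an error.
* Dropout uses inverted scaling, so inference needs no rescaling.
* The loss guards against `log(0)` by flooring probabilities at 1e-300;
  non-finite scores abort training with diagnostics.

## Known limitations

* The localizer assumes one dominant tumor; multifocal disease keeps
  only the best-supported chain.
* Tumors occupying a very large brain fraction inflate the expected
  area and erode the benefit of localization — a limitation the
  original method shares.
* Per-voxel patch classification, even with the dense engine, is slower
  than fully-convolutional encoder-decoder designs; the choice follows
  the method being implemented, not efficiency.
* The phantom generator's simplifications listed above bound what the
  tests can certify about clinical data.
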