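# cascadeseg

Multi-modal MRI brain tumor segmentation in R, for researchers who need
a transparent, fully scriptable implementation of localization-first
patch classification: find where the tumor can be, then classify only
there.

Glioma segmentation from the four standard MRI modalities (FLAIR, T1,
T1ce, T2) is dominated by class imbalance — tumor voxels are a few
percent of the brain — and by the cost of classifying every voxel of a
volume. `cascadeseg` implements a three-part answer:

1. **Rule-based localization.** Per axial slice, the z-scored FLAIR, T2
   and T1ce images are binarized at fractional thresholds (0.7 / 0.7 /
   0.9 of the within-brain min–max range), cleaned morphologically, and
   fused: the FLAIR and T2 masks are multiplied, and a T1ce component is
   added only if it is solid (solidity > 0.7), large (area > 500 px),
   elongated enough (major axis > 35 px) and overlaps the product mask
   by more than 20 px. Objects are then tracked across slices — a true
   tumor persists at almost the same position and size in consecutive
   slices, which a one-slice artifact cannot do — and the biggest
   confirmed object is dilated into a per-slice **expected area** that
   shrinks slice by slice away from its peak. All later work is
   restricted to this region (roughly a sixth of the brain per slice on
   the bundled phantoms).

2. **Distance-wise attention (DWA).** A deterministic scalar per slice:
   the Euclidean distance between the center of each modality's binary
   brain silhouette and the center of the expected area, normalized by
   the image row count and averaged over the four modalities. Object
   centers use run counts — `W` is the maximum over rows of the row's
   true-pixel count, `H` the column analogue, and the center is
   `(y0 + H/2, x0 + W/2)`. The scalar is appended to the CNN features
   before the classifier head.

3. **Cascade CNN.** Each voxel is classified from two 8-channel patches
   (four raw modalities + four z-scored): a 40×40 patch through a
   five-layer convolutional route (max-pooling after layers 2 and 4)
   for context, and a 15×15 patch through a two-layer route for local
   detail. Flattened features from both routes plus the DWA scalar pass
   through 7% dropout and a fully-connected head to a 4-way softmax over
   the BRATS classes (normal 0, necrosis 1, edema 2, enhancing 4), with
   softmax cross-entropy `loss_i = -log(exp(U_p) / Σ_d exp(U_d))` and
   Adam (lr 1e-4, weight decay 1e-5, batch size 2). Training patches
   are drawn class-balanced from inside the expected area; inference
   classifies exactly the expected-area voxels (a dense
   shift-and-stitch engine makes this fast and bit-equivalent to the
   patch network).

Evaluation follows the BRATS region conventions — enhancing tumor {4},
tumor core {1,4}, whole tumor {1,2,4} — with Dice, sensitivity and the
99th-percentile symmetric surface Hausdorff distance in mm.

A synthetic phantom generator (four-modality volumes with the assumed
contrast orderings, a planted tumor with a unimodal slice-area profile,
nested sub-regions, and a single-slice decoy artifact) makes the entire
pipeline testable without clinical data.

## Worked example

Train on three small phantoms and evaluate a held-out fourth:

```r
library(cascadeseg)

spec <- phantom_spec(shape = c(96L, 96L, 20L), r_max = 12, slope = 1.5,
                     artifact = list(center = NULL, radius = 16, slice = NULL))
cohort <- generate_cohort(4, spec, jitter = list(center = 3, z = 2, r = 0),
                          seed = 42)
cfg <- run_config(
  localization = localization_config(small_object_floor = 15,
                                     search_radius = 20,
                                     enlargement_radius = 8),
  train = train_config(epochs = 2L, batch_size = 4L),
  per_class_quota = 60L, seed = 42L)

res <- run_pipeline(cohort[1:3], cohort[4], cfg)
print(res$metrics, row.names = FALSE)
#>     subject region      dice sensitivity hausdorff_mm
#>  phantom004    Enh 0.8884488   0.9781977     1.414214
#>  phantom004  Whole 0.9189394   0.9946699     1.414214
#>  phantom004   Core 0.9206799   0.9838547     1.544527

localize_subject(cohort[[4]], cfg$localization)
#> <expected_area> biggest slice 11 (area 366 px), chain slices 6..15
#>   masks: 20 nonempty slices, 16567 voxels total
```

The metrics table reads: on the held-out phantom, whole-tumor overlap
with ground truth is Dice 0.92 with 99.5% of tumor voxels recovered,
and the 99th-percentile surface error is ~1.4 mm. The localization
printout shows the tracked tumor peaked at slice 11 and the expected
area confined classification to ~16.6k of the volume's 184k voxels.
With the full-size default phantoms (240×240×32) and the default
training budget the held-out whole-tumor Dice is ≈ 0.95–0.99.

`run_pipeline()` is a convenience wrapper; each stage is exported on its
own (`zscore_subject()`, `localize_subject()`, `dwa_for_slice()`,
`sample_training_set()`, `train_cascade()`, `segment_volume()`,
`evaluate_subject()`), and `inst/cli/cascadeseg.R` exposes them as shell
subcommands (`make-phantom`, `localize`, `train`, `segment`,
`evaluate`) over NIfTI files, a CSV manifest and a YAML config.

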