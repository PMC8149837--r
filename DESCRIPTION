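Package: cascadeseg
Title: Cascade CNN Brain Tumor Segmentation with Rule-Based Localization
    and Distance-Wise Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-modal MRI brain tumor segmentation built around three
    components: a rule-based localizer that finds the per-slice "expected
    area" of the tumor from thresholded FLAIR, T2 and T1ce slices using
    connected-component shape rules and cross-slice tracking; a
    deterministic distance-wise attention feature measuring the normalized
    distance between the brain and expected-area centers; and a two-route
    cascade convolutional neural network that classifies voxels into four
    tissue classes from paired global (40x40) and local (15x15)
    eight-channel patches. Includes NIfTI input/output, within-brain
    z-score normalization, Dice/sensitivity/Hausdorff-percentile
    evaluation per tumor region, and a synthetic multi-modal phantom
    generator so the whole pipeline can be exercised without clinical
    data.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
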