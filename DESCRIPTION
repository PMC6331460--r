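Package: skeletonCCA
Title: Whole-Brain Canonical Correlation Mapping of White-Matter
    Skeleton Features Against Behavioral Scores
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Association analysis between a single behavioral score and a
    high-dimensional voxelwise white-matter feature matrix (for example
    fractional-anisotropy values sampled on a TBSS skeleton). The feature
    block is reduced by truncated singular value decomposition, related to
    the score by a one-dimensional canonical correlation fit, the retained
    dimensionality is chosen by leave-one-out cross-validation, significance
    is assessed by permutation of the behavioral scores, and voxelwise
    reliability is mapped by a subject-resampling bootstrap whose per-fold
    components are Procrustes-aligned to the full-data solution, yielding
    signed bootstrap-ratio saliency maps. Includes a synthetic-cohort
    generator with a planted rank-one brain-behavior association for
    calibration and power studies, NIfTI readers and writers for skeleton
    data and saliency maps, and a study-level pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'simulate.R'
    'latent.R'
    'inference.R'
    'io.R'
    'methods-accessors.R'
    'pipeline.R'
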