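Package: fcshrink
Title: Shrinkage Prediction of Test-Retest Functional Connectivity Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seed-based resting-state functional connectivity analysis for
    scan-rescan designs. Computes seed time courses and voxelwise Pearson
    correlation maps from 4D volumes, Fisher-Z transforms them, estimates
    voxelwise measurement-error variance components and the shrinkage weight
    lambda(v) under a classical measurement-error model, and predicts each
    subject's second-session connectivity map by shrinking the subject's own
    first-session map toward the group mean (the best linear unbiased
    predictor). Includes raw, group-mean, and shrinkage predictors, mean
    squared error evaluation with Tukey outlier summaries, a synthetic-data
    generator with known ground truth, NIfTI input/output, and a reproducible
    simulate/fit/evaluate pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
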