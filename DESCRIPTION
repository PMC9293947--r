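Package: facekin
Title: Video-Based Quantification of Hypomimia from Facial Landmark Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic assessment of hypomimia (facial bradykinesia) from
    monologue video recordings. Computes twelve facial-dynamics markers over
    eight facial regions from 68-point landmark time series and grayscale
    frames: Euclidean markers (eyebrow, eyelid, lip, mouth-corner and jaw
    movement variability, scale-normalized by the inner-eye-corner distance)
    and surface markers (temporal variability of edge-highlighted image
    entropy over forehead, nose-root, lateral-canthal and cheek regions).
    Provides the cohort-level pipeline: normality-gated group tests with
    Bonferroni correction, age-controlled partial correlations, control-based
    abnormality cutoffs with affected-area counting, and leave-one-subject-out
    ridge-logistic classification with exhaustive marker-subset search, ROC
    metrics and prevalence estimation at a bounded false-positive operating
    point. A deterministic synthetic-cohort generator (animated landmarks plus
    procedurally rendered frames with ground-truth severity) makes every stage
    testable without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    png,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
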