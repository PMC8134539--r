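Package: fcstrat
Title: Functional-Connectivity Stratification and Severity Prediction for
    Multi-Site Autism Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies high-functioning autism spectrum disorder (ASD)
    cohorts into severity subgroups from resting-state functional
    connectivity (FC). Implements Spearman screening of edge-wise FC
    against ADOS subscales, canonical correlation analysis with a
    selection-aware whole-pipeline permutation null, Ward hierarchical
    clustering of canonical scores with silhouette model selection,
    agreement analysis against ADOS-cutoff partitions, graded-change
    biomarker tests with Benjamini-Hochberg FDR control, and support
    vector machine prediction of ADOS severity under cross-validation.
    Includes a multi-site synthetic cohort generator with planted
    canonical structure, severity subgroups and marker edges, so every
    stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    cluster,
    e1071,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
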