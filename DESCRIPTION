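Package: TBImiR
Title: Biofluid miRNA Biomarker Discovery for Mild Traumatic Brain Injury
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for discovering saliva and serum
    microRNA biomarkers of mild traumatic brain injury (mTBI) in contact-sport
    cohorts with longitudinal pre/post-exposure sampling. Implements
    reference-miRNA log2 normalization and within-subject baseline
    differencing, head-impact dose (hits-to-the-head) and temporal-bin cohort
    design, feature-wise two-way fixed-effects screens with
    Benjamini-Hochberg control, stepwise panel selection with logistic
    classification and Monte-Carlo cross-validated AUC, an explicit
    rule-based detector for acute-saliva and delayed-serum temporal response
    patterns, correlation and protein-panel statistics including below-LOD
    substitution, and joint molecular-functional principal-axis factor
    analysis with quartimax rotation. A negative-binomial synthetic cohort
    generator with planted effects provides ground truth for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Transcriptomics, Sequencing, DifferentialExpression,
    Classification, Normalization
RoxygenNote: 7.3.3
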