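Package: emlscreen
Title: Ensemble Machine Learning Screening from Serum GC-MS Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for serum metabolomics screening of
    endometrial cancer from GC-MS peak tables: analytical batch quality
    control (blank, standard mix, pooled and duplicate injections),
    feature presence filtering, internal-standard normalization with log
    transform and autoscaling, univariate volcano analysis, feature
    screening with genetic-algorithm wrapper selection, grid-search
    training of seven classifier families, PLS-DA diagnostics (VIP
    scores, R2/Q2, permutation test), and an ensemble weighted-voting
    score with Youden-index thresholding, DeLong AUC confidence
    intervals, and a full diagnostic-metric panel. A synthetic cohort
    generator with planted fold-change effects makes every stage
    testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    glmnet,
    nnet,
    rpart,
    randomForest,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mixOmics,
    yaml
Config/testthat/edition: 3
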