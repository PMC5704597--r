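Package: concordkit
Title: Concordance and Performance Evaluation of Missense Variant Pathogenicity Predictors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating in silico missense-variant pathogenicity
    predictors against clinical assertions. Harmonizes heterogeneous predictor
    outputs (numeric scores and categorical labels) into direction-aligned
    scores and binary calls, computes pairwise and exhaustive k-wise
    combination concordance and false-concordance statistics against
    ClinVar-style labels, compares predictors by ROC AUC with DeLong and
    stratified-bootstrap inference, clusters predictors by multiscale-bootstrap
    hierarchical clustering with approximately unbiased (AU) support values,
    and constructs circularity-controlled and stratified evaluation cohorts.
    A synthetic prediction-matrix generator with known ground truth makes every
    stage testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
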