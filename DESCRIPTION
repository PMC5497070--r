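Package: raschcrowd
Title: Rasch-Weighted Consensus Scoring for Crowdsourced Binary Diagnostic Labels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aggregates crowdsourced binary diagnostic classifications
    (e.g. normal/abnormal grades of retinal fundus photographs) into
    consensus labels. Estimates per-worker ability and per-item difficulty
    from a sparse correctness matrix by joint maximum-likelihood estimation
    of the dichotomous Rasch model, converts abilities into centile-truncated
    odds-scale vote weights, and scores each item by the weighted sum of its
    recoded (+1/-1) votes. Provides a majority-vote baseline, empirical
    ROC/AUROC analysis with DeLong confidence intervals and paired tests,
    logistic calibration of the consensus score, constrained diagnostic
    cut-point selection, leave-one-item-out jackknife cross-validation, and
    a synthetic crowd simulator for parameter-recovery and benchmarking
    studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pROC,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
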