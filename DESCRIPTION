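Package: cytoresponse
Title: Early-Response Single-Cell Signaling Analysis for Mass Cytometry Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch-standardizes multiplexed mass cytometry samples against
    shared reference aliquots using anchored quantile normalization, clusters
    cells with a self-organizing map followed by consensus metaclustering,
    extracts per-metacluster 90th-percentile signaling features across
    treatment timepoints, selects survival-predictive features by nested
    leave-one-out LASSO-Cox regression, and stratifies patients by median
    split with Kaplan-Meier/log-rank analysis. Includes a synthetic cohort
    generator with known ground truth (cell populations, batch distortions,
    treatment response, survival mechanism) so the whole pipeline can be
    validated end to end, plus manual bi-axial blast gating and ex vivo
    drug-sensitivity (DSS/sDSS) scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    withr,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
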