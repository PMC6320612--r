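Package: emgscore
Title: Automated Clinical Scoring of Surface EMG from Functional Evaluations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates ordinal clinical scores (activity level, spasm
    severity, amplitude modulation, laterality of activity) from surface
    electromyographic recordings collected during static and dynamic
    functional-evaluation tests. Implements the full analysis chain:
    elliptic band-pass filtering and envelope extraction, periodogram
    band-energy and burst-detection features, class-rebalanced averaged
    linear regression, bagged regression trees with out-of-bag permutation
    importance, 10-fold cross-validated score estimation, and the
    evaluation metrics (RMSE, regression coefficient with 95% confidence
    interval, per-class summaries). A synthetic surface-EMG generator
    produces score-annotated cohorts with the statistical structure the
    method assumes, so the whole pipeline is testable without access to
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    rpart,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    withr,
    optparse
Config/testthat/edition: 3
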