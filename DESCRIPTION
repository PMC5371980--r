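Package: combipanel
Title: Combinatorial Selection and ROC Evaluation of Diagnostic Marker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustive combinatorial analysis of diagnostic biomarker panels
    in two-class (case/control) studies. Every non-empty subset of a marker
    panel is scored by sensitivity and specificity under a threshold/minimum-
    features stringency rule, the best ("gold") combinations are selected by
    user-chosen sensitivity/specificity filters, and candidate panels are
    evaluated by ROC curves with trapezoidal AUC, Youden optimal cutoffs,
    prediction summaries, stratified k-fold cross-validation and
    label-permutation significance testing. Includes optional log/autoscale/
    Pareto preprocessing, a synthetic two-class data generator for testing,
    plot helpers and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
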