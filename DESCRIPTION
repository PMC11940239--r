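Package: metaboscreen
Title: Case-Control Screening and Random Forest Validation for
    Metabolomics Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential screening and machine-learning validation of
    untargeted metabolomics feature tables in a case-control design.
    Provides median-based sample normalization, log transformation and
    autoscaling; fold-change/Welch-t volcano screening with
    Benjamini-Hochberg false discovery rate control; a repeated nested
    cross-validation Random Forest scaffold with a Y-scrambled null arm,
    permutation 1-AUC feature importance and percentile bootstrap
    confidence intervals; cohort-characteristics tables (Fisher's exact,
    Wilcoxon rank-sum); and a synthetic-data generator that plants known
    multiplicative group effects in log-normal abundance tables so the
    whole pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ranger,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
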