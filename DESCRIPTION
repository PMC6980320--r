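Package: treestack
Title: Tree-Level Stacked Ensembles for Multi-Study Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds cross-study ensemble predictors from random forests trained
    on separate studies. Member forests, or the individual trees extracted from
    them, are combined with non-negative ridge-penalized stacking weights that
    reward cross-study prediction within the training collection. Includes a
    simulation engine for multi-study data with controlled feature-distribution
    and feature-effect heterogeneity (coefficient perturbation, optional
    interaction terms present in a subset of studies), tree-structure and
    permutation-importance diagnostics linking ensemble weights to tree
    anatomy, and scenario-grid evaluation with RMSE and log-loss summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
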