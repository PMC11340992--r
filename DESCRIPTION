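Package: conncpm
Title: Connectome-Based Predictive Modeling with Computational Lesioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for connectome-based predictive modeling (CPM) of
    individual differences from functional connectivity matrices:
    Fisher-z connectome construction from node time series, cohort-level
    node harmonization and motion quality control, leave-one-out CPM
    training with consensus edge masks, network-strength scoring,
    covariate-adjusted partial Spearman associations with biomarkers and
    cognitive composites, Steiger's Z tests for dependent correlations,
    and computational lesioning of canonical brain networks. Includes a
    seeded synthetic-cohort generator with planted edge-level signal and
    a motion confound for power analysis and method validation, and an
    end-to-end reproducible pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
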