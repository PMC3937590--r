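Package: pharmsig
Title: Multi-Omic Drug-Response Signatures for Cancer Cell-Line Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models therapeutic compound response in cancer cell-line panels
    from raw growth-inhibition plates to patient-level treatment ranking.
    Computes GI50/TGI response measures with the NCI two-branch percent-growth
    convention, dichotomizes response at the per-compound mean GI50 over a core
    line set, trains weighted least-squares support vector machines and random
    forests on multi-omic feature matrices (expression, copy number,
    methylation, protein, mutation) with grid-search feature optimization and
    multi-split AUC evaluation, compares predictive value across data types and
    against transcriptional-subtype baselines, and applies trained signatures
    to tumor cohorts with mixture-model probability cutoffs, tri-level response
    status, and dynamic-range-aware compound ranking. Includes a synthetic
    panel generator with planted ground truth so every stage is testable
    without external data.
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
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    generics,
    withr,
    mclust,
    ranger,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
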