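Package: shmctm
Title: Shared Multicellular Tumor Models and Mortality-Associated Gene
    Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives a consensus multicellular tumor model from per-cancer
    cell-cell interaction inferences and tests gene signatures extracted
    from it for association with 10-year all-cause mortality. Provides a
    simplified ligand-activity statistic (Pearson correlation of prior
    regulatory potential against receiver differential-expression
    membership), cross-cancer consensus rules for shared upstream
    regulators and downstream targets, interaction-count clustering for
    signature prioritization, rank-based single-sample gene-set scoring
    and mean-protein scoring with missingness QC and KNN imputation, and
    Cox proportional-hazards / Kaplan-Meier survival machinery. A
    synthetic-data generator emulates the derived differential-expression
    tables, regulatory prior, and survival cohorts the analysis assumes,
    so the whole pipeline is testable without restricted data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
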