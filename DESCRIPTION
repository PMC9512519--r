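Package: metabopipe
Title: Streamlined Quality Control, Normalization and Association Analysis
    for Metabolomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native workflow for population-scale metabolomics:
    a samples-by-metabolites container with feature and sample annotations and
    an append-only processing log; quality control (missing-rate filtering,
    outlier detection with winsorization, half-minimum/median/zero/KNN
    imputation); batch-median, pooled-QC-sample, nearest-QC-sample and LOESS
    run-order normalization; log, Pareto, autoscale and rank-based inverse
    normal transformations; PCA, UMAP and t-SNE embeddings; and metabolite-wide
    association scans (linear, logistic, Cox proportional hazards, linear and
    logistic mixed models) with multiple-testing adjustment. Includes a
    synthetic-data generator with known ground truth (batch effects, run-order
    drift, non-random missingness, injected outliers, phenotype effects) for
    end-to-end validation, plus a declarative pipeline runner and command-line
    interface.
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
    lme4,
    lmerTest,
    parallel,
    purrr,
    readr,
    readxl,
    rlang,
    Rtsne,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    uwot,
    withr,
    yaml
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
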