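Package: cortseq
Title: Global Transcriptome Accounting and Corticosterone Response Analysis
    for Bulk RNA-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the global assessment of a bulk RNA-seq transcriptome
    and for the analysis of glucocorticoid (corticosterone) treatment effects
    on it. Provides counts-per-million expression tiers and transcript-share
    accounting, duplicate gene-symbol merging, marker-based dataset
    validation, expression filtering with the median-library-size threshold
    rule, a self-contained trimmed-mean-of-M-values normalization and
    negative-binomial testing stage (two-group exact test and batch-adjusted
    log-linear model), cross-timepoint replicability and Venn summaries,
    cell-expression-specificity scoring against a brain cell atlas,
    net transcript-budget computation, hierarchical clustering with
    uncentered correlation and Cluster 3.0 compatible CDT/GTR output,
    referential gene-list comparison with direction-preference rules, and a
    negative-binomial count simulator that reproduces the statistical
    structure the analysis assumes.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    edgeR,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
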