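Package: memorytc
Title: Transcriptional Memory Analysis of Heat-Shock Time-Course RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying transcriptional memory in stress time-course
    RNA-seq experiments with a factorial strain-by-memory-by-time design.
    Simulates negative binomial count matrices with known gene-wise time
    trends and memory, strain and interaction modulation; performs low-count
    filtering, trimmed-mean-of-M-values (TMM) normalization and PCA quality
    control; calls pairwise differential expression with an empirical
    noise-distribution probability and five-level fold-change categories;
    fits a per-gene polynomial time-course regression with
    hierarchy-respecting backward stepwise refinement; classifies memory,
    strain and interaction effects as enhanced, dampened or reversed;
    summarizes overlaps and gene-set over-representation (Fisher's exact
    test, Benjamini-Hochberg); and quantifies qPCR validation data with the
    2^-ddCt method and paired t-tests.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    edgeR,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
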