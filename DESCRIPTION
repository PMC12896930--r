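Package: mirstage
Title: Stage-Wise NanoString nCounter miRNA Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for stage-stratified analysis of
    NanoString nCounter miRNA panel counts: per-sample quality control using
    spike-in controls, background correction against negative probes, two
    comparable normalization pipelines (control-based scaling with or without
    trimmed-mean-of-M-values between-sample normalization) with relative log
    expression diagnostics, empirical-Bayes moderated-t differential
    expression with stage-wise Venn partitioning, cumulative miRNA-to-target
    regulatory scoring with exportable networks, hypergeometric gene-set
    over-representation, and Spearman correlation of expression with coded
    clinicopathological variables. Includes a calibrated synthetic-data
    generator emulating an nCounter-style human miRNA panel so the whole
    pipeline is testable without proprietary raw data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
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
    fgsea,
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
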