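Package: catchub
Title: Cross-Stage Analysis of Promoter H2AK119ub1 Dynamics in Oocytes and
    Early Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline for low-input histone-modification
    ChIP-seq across the oocyte-to-embryo transition. Provides sliding-bin
    signal tracks with background-anchored cross-stage normalization (no
    spike-ins), a broad-domain peak caller with quality filters, promoter
    quantification and negative-binomial differential enrichment that
    defines stage-wise "ub-down"/"ub-up" gene sets, k-means co-occupancy
    clustering of promoters across histone marks, zygotic genome activation
    (ZGA) gene-set logic on FPKM tables, strand-aware TSS metaplots, and
    absolute RT-qPCR ratio computations with primer-efficiency correction.
    A synthetic-data generator with planted ground truth makes every stage
    testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    DESeq2,
    optparse
Config/testthat/edition: 3
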