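Package: cernet
Title: Competing Endogenous RNA Network Analysis for Two-Group Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds and analyses competing endogenous RNA (ceRNA) networks
    from pre-summarized expression matrices. Provides expression
    preprocessing (zero-expression filtering, quantile normalization, log2
    transform, probe-to-gene collapse, mRNA/lncRNA biotype split), two-group
    differential expression with Welch or paired t-tests and
    Benjamini-Hochberg FDR, dual-database miRNA-target integration,
    tripartite lncRNA-miRNA-mRNA network construction with degree-based hub
    ranking and per-lncRNA subnetwork extraction, hypergeometric gene-set
    over-representation against GMT libraries, and RT-qPCR relative
    quantification by the 2^-deltaCt method. A synthetic-data module
    generates all pipeline inputs with planted differential expression, hub
    lncRNAs and enriched gene sets, so the whole pipeline can be exercised
    and calibrated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
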