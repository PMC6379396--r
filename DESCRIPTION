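Package: lncatlas
Title: Long Non-Coding RNA Atlas Construction for the Humoral Immune Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for building an atlas of long
    non-coding RNAs (lncRNAs) across the B cell maturation stages of the
    humoral immune response (naive B, centroblast, centrocyte, memory B,
    tonsillar and bone-marrow plasma cells). Implements the novel-lncRNA
    discovery cascade (length, expression, repeat-overlap and
    coding-potential filters with antisense/intergenic positional
    classification), genome transcription accounting, expression analytics
    (TPM normalization, differential-expression thresholding, the tissue
    specificity index tau, trajectory k-means, PCA, and a bootstrapped
    neighbor-joining phylogeny of cell types), GREAT-style regulatory-domain
    association of lncRNAs with coding genes, chromatin-state feature
    summaries and spectral clustering of lncRNAs into functional classes,
    enhancer and super-enhancer calling with eRNA identification, a
    bidirectional-transcription score from stranded read-start coverage, a
    permutation null for genomic overlap enrichment, and circRNA back-splice
    junction filtering with immunoglobulin-locus partitioning. A seeded
    synthetic-data generator with planted ground truth exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    generics,
    withr,
    stats,
    tools,
    utils,
    methods,
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    DESeq2,
    knitr
Config/testthat/edition: 3
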