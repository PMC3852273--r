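Package: promarch
Title: Promoter Architecture of Co-Expressed Genes from Positional Motif Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the promoter architecture of co-expressed plant genes from
    the position and orientation of transcription-factor binding sites relative
    to the translation start site (TLS). From a normalized expression matrix and
    a genome, the package derives structure-specific gene sets, selects
    non-redundant over-represented motifs by k-mer-vector clustering and a
    hypergeometric group-specificity score, trains a support vector machine on
    strand-aware average TFBS-to-TLS distances with leave-one-out
    cross-validation, extracts bin-by-strand motif patterns from correctly
    classified promoters, and scans a genome for genes whose promoters satisfy
    those patterns. A fully deterministic synthetic-data generator provides
    ground truth (implanted motif sites, planted expression groups) for every
    stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    cluster,
    dplyr,
    e1071,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
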