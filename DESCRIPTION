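Package: regulonscan
Title: Promoter Motif Scanning and Regulon Discovery from Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers the core regulon of a transcription factor by combining
    position-weight-matrix scanning of upstream promoter regions with
    fold-change classification of replicated FPKM expression profiles.
    Promoter windows are scored with a normalized log-likelihood ("stringency")
    statistic against genomic background frequencies; genes are binned by
    fold change across strain/condition contrasts, clustered hierarchically,
    tested for hierarchical functional-category enrichment, and intersected
    with motif-bearing genes to yield a core-regulon table. A synthetic-data
    module generates genomes, promoters with planted binding sites, and
    replicated expression matrices with known ground truth so that every
    stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
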