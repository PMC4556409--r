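Package: smartanno
Title: Gene Annotation from Full-Length Transcript Sequencing Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for evidence-based eukaryotic gene annotation from
    single-molecule full-length cDNA reads and short-read mRNA-seq coverage.
    Classifies full-insert cDNA reads (synthesis primers and poly(A) tail),
    validates predicted gene models against spliced long-read alignments,
    derives new gene models by intron-chain clustering of aligned reads,
    reduces background noise in mRNA-seq coverage tracks, generates extrinsic
    evidence hints for an external gene predictor, transfers stable gene
    identifiers between annotation versions, and evaluates prediction
    accuracy. Includes a deterministic simulator of annotated genomes,
    full-insert reads, and noisy expression data so that every stage can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    dplyr (>= 1.1.0),
    methods,
    rtracklayer,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
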