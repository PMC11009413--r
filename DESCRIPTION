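Package: clipscape
Title: Downstream Analysis of iCLIP Binding Sites, Motif Enrichment, and
    Reference-Gene-Normalized Differential Translation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable downstream pipeline for RNA-binding-protein iCLIP
    studies in transcript coordinates: binding-site expansion, crosslink-event
    filtering, site maxima, binding-strength classification, positional trimer
    enrichment around site maxima with hierarchical clustering into motif
    sets, proportional metatranscript profiling over 5'UTR/CDS/3'UTR,
    reference-gene-normalized differential RNA abundance and ribosome
    occupancy with a negative-binomial Wald test, poly(A) tail-length
    summarization stratified by binding-site load, and peak-overlap analysis.
    Includes a fully deterministic synthetic-data generator that emulates the
    sequencing inputs (motif-planted transcriptomes, condition-dependent
    crosslink tracks, negative-binomial count matrices with binding-coupled
    translational repression, and per-read poly(A) tail estimates) so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
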