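Package: pausescan
Title: Promoter-Proximal RNA Polymerase II Pausing Scores from ChIP-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate transcriptionally paused genes from RNA
    polymerase II ChIP-seq read positions. Computes a per-gene stalling
    index (the log2 ratio of the maximal 600 bp window read count near the
    transcription start site to the median read count over non-overlapping
    600 bp gene-body windows), locates the local minimum separating the two
    modes of the stalling-index distribution by kernel density estimation,
    and intersects high-index genes with early/transient expression
    induction to call candidate paused immediate-early genes. Includes
    relative qPCR quantification by the 2^-ddCt method and a synthetic-data
    generator with planted gene classes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    methods,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
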