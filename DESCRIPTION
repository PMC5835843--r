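Package: isomiRpipe
Title: IsomiR Calling, Quantification and Differential Analysis for Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A small-RNA sequencing analysis pipeline for microRNA isoform
    (isomiR) studies: 3'-adapter trimming and quality filtering of FASTQ
    reads, assignment of reads to mature miRNAs and isomiR classes (5'/3'
    offsets, templated versus non-templated additions) against hairpin
    precursor references, reads-per-million normalization with abundance
    filters, isomiR proportion and 5p/3p arm-ratio summaries, and
    replicate-level differential testing of miRNA abundance and isomiR
    composition. Includes a seeded synthetic-library generator with
    machine-readable ground truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
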