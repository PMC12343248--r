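Package: splicedrop
Title: Barnyard Cell Calling and Splice-Junction Analysis for Droplet Full-Length scRNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for droplet-based single-cell full-length
    transcriptome (scFL) experiments that mix cells of two species (a
    "barnyard" design). Implements rank-based empty-droplet thresholding and
    five-category species classification of droplets, cross-genome
    ambiguous-read and barcode-aware duplicate filtering, gene-body coverage
    profiling, genomic-region read assignment, splice-junction extraction and
    annotation-based classification, skipped-exon quantification, TPM
    quantification with pseudo-bulk aggregation, and Pearson correlation
    between expression profiles. A seeded two-species droplet simulator with
    full per-read and per-droplet ground truth drives testing, so the whole
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
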