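Package: editmux
Title: Error-Tolerant Search, Demultiplexing and Barcode Discovery for
    Noisy Sequencing Reads
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Locates known flanking sequences in noisy long- and short-read
    sequencing data by bounded semi-global Levenshtein alignment with a
    wildcard barcode/UMI region, error-corrects cell barcodes against a
    whitelist under a unique-lowest-distance rule, detects and splits
    chimeric reads by iterative masking on both strands, discovers barcodes
    de novo from flank-adjacent sequence, and calls true cell barcodes from
    the knee of the rank-frequency curve via a rolling-window derivative in
    log-log space. Includes streaming FASTA/FASTQ input and output (plain or
    gzip, file or standard streams), a read simulator with configurable
    substitution, insertion and deletion error rates, chimera formation and
    strand flips, and a command-line interface for pipeline use.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse,
    jsonlite,
    withr
biocViews: SingleCell, Transcriptomics, LongRead, Sequencing, Alignment,
    Preprocessing
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
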