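Package: fqsmooth
Title: Reference-Based Lossy Smoothing of FASTQ Quality Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Smooths Phred quality scores in FASTQ files against a reference
    genome. An FM-index (Burrows-Wheeler transform plus count and rank
    tables) built over the reference answers k-mer membership queries with
    up to one mismatch; bases whose covering k-mers are all concordant with
    the reference have their quality replaced by a constant high value,
    which lowers quality-stream entropy and improves compressibility while
    leaving suspect bases untouched. Includes streaming FASTQ input/output
    that preserves record order, an Illumina-like read simulator with a
    known-error truth channel, evaluation utilities (order-0 quality
    entropy, compression ratios under gzip, bzip2 and xz), and a
    command-line interface for pipe-based processing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
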