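# Per-base quality smoothing against the FM-index dictionary.
#
# Rule precedence per base (fixed, test-pinned):
#   (1) fast path:        quality >  higher_threshold -> replacement quality,
#                         no dictionary search is needed for this rule;
#   (2) low-quality keep: quality <  lower_threshold  -> unchanged;
#   (3) uncovered keep:   no queried k-mer covers the base -> unchanged;
#   (4) concordance:      every queried covering k-mer is found and the base
#                         is concordant in each -> replacement quality;
#                         otherwise unchanged (discordant keep).
# Comparisons are strict on both thresholds: "below" the lower threshold and
# "above" the higher one.  A k-mer is queried only if every base it covers
# has quality >= lower_threshold and an A/C/G/T call, which also acts as a
# read-tail trimming mechanism.

#' Smoothing parameters
#'
#' Defaults follow the standard configuration: `k = 32`, one mismatch
#' allowed, lower threshold 6 (error probability ~0.25), higher threshold 40
#' and replacement quality 40 (`'I'`, the top of the Illumina 0-41 range),
#' Phred+33 encoding.
#'
#' @param k k-mer length (>= 2).
#' @param max_mismatches substitutions tolerated in a dictionary hit (0 or 1).
#' @param lower_threshold Phred value below which qualities are never touched
#'   and covering k-mers are not queried.
#' @param higher_threshold Phred value above which qualities are replaced
#'   without consulting the dictionary.
#' @param replacement_quality Phred value written at smoothed positions.
#' @param offset quality encoding offset (33 for Phred+33).
#' @param both_strands query the reverse complement of each k-mer as well.
#' @return an object of class `smoothing_params`.
#' @export
smoothing_params <- function(k = 32L, max_mismatches = 1L,
                             lower_threshold = 6L, higher_threshold = 40L,
                             replacement_quality = 40L, offset = 33L,
                             both_strands = TRUE) {
  p <- list(
    k = as.integer(k), max_mismatches = as.integer(max_mismatches),
    lower_threshold = as.integer(lower_threshold),
    higher_threshold = as.integer(higher_threshold),
    replacement_quality = as.integer(replacement_quality),
    offset = as.integer(offset), both_strands = isTRUE(both_strands)
  )
  if (is.na(p$k) || p$k < 2L) format_error("k must be an integer >= 2")
  if (!p$max_mismatches %in% c(0L, 1L)) {
    format_error("max_mismatches must be 0 or 1")
  }
  if (p$lower_threshold < 0L || p$lower_threshold > p$higher_threshold ||
      p$higher_threshold > 93L) {
    format_error("thresholds must satisfy 0 <= lower <= higher <= 93")
  }
  if (p$replacement_quality < 0L || p$replacement_quality > 93L) {
    format_error("replacement_quality must be in [0, 93]")
  }
  if (p$offset < 33L || p$offset > 64L) {
    format_error("offset must be in [33, 64]")
  }
  structure(p, class = "smoothing_params")
}

#' Phred error probability
#'
#' @param q Phred quality value(s) in `[0, 93]`.
#' @return `10^(-q/10)`, the base-call error probability.
#' @export
#' @examples
#' phred_error_probability(6)   # the "'" character at Phred+33
phred_error_probability <- function(q) {
  if (any(is.na(q)) || any(q < 0 | q > 93)) {
    format_error("Phred values must lie in [0, 93]")
  }
  10^(-q / 10)
}

as_single_record <- function(record) {
  if (is.data.frame(record)) {
    if (nrow(record) != 1L) format_error("expected a single record")
    record <- as.list(record)
  }
  if (is.null(record$sequence) || is.null(record$quality) ||
      nchar(record$sequence) != nchar(record$quality)) {
    format_error("record must carry sequence and quality of equal length")
  }
  record
}

#' Which k-mers of a read are queried?
#'
#' A k-mer starting at (0-based) position `i` is queried iff every base in
#' `[i, i+k)` has quality at or above the lower threshold and an A/C/G/T
#' call.  Low-quality bases thereby disqualify every covering k-mer, which
#' trims low-quality read tails.
#'
#' @param record a single read (list or one-row record frame with
#'   `sequence` and `quality`).
#' @param params a [smoothing_params()] object.
#' @return logical vector of length `n - k + 1` (element `i` is the k-mer
#'   starting at 0-based position `i - 1`); length 0 when the read is shorter
#'   than `k`.
#' @export
queried_kmer_mask <- function(record, params = smoothing_params()) {
  record <- as_single_record(record)
  n <- nchar(record$sequence)
  k <- params$k
  if (n < k) return(logical(0))
  qv <- as.integer(charToRaw(record$quality)) - params$offset
  bc <- encode_dna(record$sequence)
  ok <- qv >= params$lower_threshold & bc %in% ACGT_CODES
  cs <- c(0L, cumsum(!ok))
  (cs[(k + 1L):(n + 1L)] - cs[1L:(n - k + 1L)]) == 0L
}

smoothing_label_names <- c("fastpath", "kept_low_quality", "kept_uncovered",
                           "smoothed", "kept_discordant")

new_smoothing_report <- function(counters) {
  structure(as.list(counters), class = "smoothing_report")
}

combine_reports <- function(a, b) {
  new_smoothing_report(mapply(`+`, unclass(a), unclass(b), SIMPLIFY = TRUE))
}

#' @export
print.smoothing_report <- function(x, ...) {
  cat("smoothing report\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' @export
format.smoothing_report <- function(x, ...) {
  paste(names(x), vapply(unclass(x), format, character(1)),
        sep = "\t", collapse = "\n")
}

#' Smooth a single read
#'
#' @param record a single read (list or one-row record frame).
#' @param index an `fm_index` built over the reference dictionary.
#' @param params a [smoothing_params()] object.
#' @return list with `record` (quality rewritten, everything else untouched)
#'   and `labels`, a character vector naming the rule that fired at each
#'   base: `"fastpath"`, `"kept_low_quality"`, `"kept_uncovered"`,
#'   `"smoothed"` or `"kept_discordant"`.
#' @export
smooth_read <- function(record, index, params = smoothing_params()) {
  record <- as_single_record(record)
  stopifnot(inherits(index, "fm_index"))
  res <- smooth_reads_cpp(
    index$bwt, index$occ, index$occ_step, index$counts,
    record$sequence, record$quality,
    params$k, params$max_mismatches, params$both_strands,
    params$lower_threshold, params$higher_threshold,
    params$replacement_quality, params$offset, TRUE
  )
  record$quality <- res$quality[[1L]]
  list(record = record,
       labels = smoothing_label_names[res$labels[[1L]]],
       report = new_smoothing_report(res$counters))
}

#' Smooth a frame of reads
#'
#' Processes records independently and returns them in input order.
#'
#' @param records a record frame as returned by [read_fastq()].
#' @param index an `fm_index`.
#' @param params a [smoothing_params()] object.
#' @return list with `records` (qualities rewritten) and `report`, a
#'   `smoothing_report` whose per-base counters partition all processed
#'   bases.
#' @export
smooth_stream <- function(records, index, params = smoothing_params()) {
  stopifnot(inherits(index, "fm_index"), is.data.frame(records))
  res <- smooth_reads_cpp(
    index$bwt, index$occ, index$occ_step, index$counts,
    records$sequence, records$quality,
    params$k, params$max_mismatches, params$both_strands,
    params$lower_threshold, params$higher_threshold,
    params$replacement_quality, params$offset, FALSE
  )
  out <- records
  out$quality <- res$quality
  list(records = out, report = new_smoothing_report(res$counters))
}

#' Smooth a FASTQ stream end to end
#'
#' Streams `input` to `output` chunk-wise (memory bounded per chunk, record
#' order preserved), smoothing each read against `index`.  The report is
#' printed to the diagnostic stream (never to standard output, which carries
#' FASTQ bytes only) and optionally written as a tab-separated sidecar file.
#'
#' @param input,output FASTQ path (optionally `.gz`), `"-"` for the standard
#'   streams, or open connections.
#' @param index an `fm_index`.
#' @param params a [smoothing_params()] object.
#' @param chunk_size records per chunk.
#' @param report_path optional path for a machine-readable report sidecar.
#' @param quiet suppress the diagnostic-stream summary.
#' @return the accumulated `smoothing_report`, invisibly.
#' @export
smooth_fastq <- function(input, output, index, params = smoothing_params(),
                         chunk_size = 5000L, report_path = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(index, "fm_index"))
  res <- fastq_chunk_apply(
    input, output,
    function(recs) {
      sm <- smooth_stream(recs, index, params)
      structure(sm$records, extra = sm$report)
    },
    chunk_size = chunk_size
  )
  report <- Reduce(combine_reports, res$extras,
                   new_smoothing_report(stats::setNames(
                     rep(0, 10L),
                     c("reads_processed", "bases_total", "bases_smoothed",
                       "bases_kept_low_quality", "bases_kept_discordant",
                       "bases_kept_uncovered", "bases_fastpathed",
                       "kmers_queried", "kmers_skipped", "kmers_found")
                   )))
  if (!quiet) message(format(report))
  if (!is.null(report_path)) {
    writeLines(format(report), report_path)
  }
  invisible(report)
}
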