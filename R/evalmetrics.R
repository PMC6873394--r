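# Quantifying the effect of smoothing: order-0 entropy of the quality
# stream, distinct-symbol counts, compression ratio under general-purpose
# compressors (gzip/DEFLATE, bzip2, xz/LZMA at their default levels), and an
# error-preservation check against a simulation's truth channel.

#' Order-0 Shannon entropy of the quality stream
#'
#' @param x a FASTQ record frame (as from [read_fastq()]) or a character
#'   vector of quality strings.
#' @return entropy in bits per quality symbol of the concatenated stream.
#' @export
#' @examples
#' quality_entropy(c("IIII", "IIII"))  # 0 bits
quality_entropy <- function(x) {
  q <- if (is.data.frame(x)) x$quality else x
  if (length(q) == 0L) format_error("empty input")
  tab <- tabulate(as.integer(charToRaw(paste(q, collapse = ""))), 256L)
  if (sum(tab) == 0L) format_error("empty quality stream")
  p <- tab[tab > 0] / sum(tab)
  -sum(p * log2(p))
}

distinct_quality_symbols <- function(x) {
  q <- if (is.data.frame(x)) x$quality else x
  sum(tabulate(as.integer(charToRaw(paste(q, collapse = ""))), 256L) > 0L)
}

#' Compression ratio of a file under a general-purpose compressor
#'
#' Ratio is uncompressed size / compressed size.  Compressors run in-memory
#' at their default level.  When the file looks like FASTQ, the quality
#' stream's order-0 entropy and distinct-symbol count are reported as
#' diagnostics.
#'
#' @param path file to measure.
#' @param compressor `"gzip"` (DEFLATE), `"bzip2"` or `"xz"` (LZMA).
#' @param fastq parse the file as FASTQ for the quality diagnostics; by
#'   default guessed from the file suffix.
#' @return an object of class `compression_summary` with fields
#'   `uncompressed_bytes`, `compressed_bytes`, `ratio`, `compressor_name`,
#'   `level`, `entropy_bits_per_symbol` and `distinct_quality_symbols`.
#' @export
compression_ratio <- function(path,
                              compressor = c("gzip", "bzip2", "xz"),
                              fastq = grepl("\\.(fastq|fq)(\\.gz)?$", path,
                                            ignore.case = TRUE)) {
  compressor <- match.arg(compressor)
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  bytes <- readBin(path, raw(), file.size(path))
  comp <- memCompress(bytes, type = compressor)
  ent <- NA_real_
  ds <- NA_integer_
  if (isTRUE(fastq)) {
    recs <- read_fastq(path)
    ent <- quality_entropy(recs)
    ds <- distinct_quality_symbols(recs)
  }
  structure(
    list(
      uncompressed_bytes = length(bytes), compressed_bytes = length(comp),
      ratio = length(bytes) / length(comp), compressor_name = compressor,
      level = "default", entropy_bits_per_symbol = ent,
      distinct_quality_symbols = ds
    ),
    class = "compression_summary"
  )
}

#' @export
print.compression_summary <- function(x, ...) {
  cat(sprintf(
    "<compression_summary> %s: %d -> %d bytes (ratio %.3f)\n",
    x$compressor_name, x$uncompressed_bytes, x$compressed_bytes, x$ratio
  ))
  invisible(x)
}

#' Are error-position qualities preserved by smoothing?
#'
#' Cross-references a simulation truth table with the original and smoothed
#' FASTQ files and counts, over all true error positions, how many qualities
#' were kept, raised or lowered by smoothing.
#'
#' @param truth_path tab-separated truth table from [write_simulation()].
#' @param original_path,smoothed_path row-aligned FASTQ files.
#' @return an object of class `smoothing_fidelity`: counts `error_positions`,
#'   `kept`, `raised`, `lowered` (which partition the error positions) and
#'   `kept_fraction`.
#' @export
smoothing_fidelity <- function(truth_path, original_path, smoothed_path) {
  tr <- read.delim(truth_path, stringsAsFactors = FALSE,
                   colClasses = c(error_positions = "character"))
  orig <- read_fastq(original_path)
  smth <- read_fastq(smoothed_path)
  if (nrow(orig) != nrow(tr) || nrow(smth) != nrow(tr)) {
    format_error("truth, original and smoothed files differ in record count")
  }
  oid <- sub("\\s.*$", "", orig$header)
  sid <- sub("\\s.*$", "", smth$header)
  if (!identical(oid, tr$read_id) || !identical(sid, tr$read_id)) {
    format_error("read id mismatch between truth and FASTQ files")
  }
  kept <- raised <- lowered <- total <- 0L
  has <- which(nzchar(tr$error_positions))
  for (i in has) {
    pos <- as.integer(strsplit(tr$error_positions[i], ",", fixed = TRUE)[[1]]) + 1L
    oq <- as.integer(charToRaw(orig$quality[i]))[pos]
    sq <- as.integer(charToRaw(smth$quality[i]))[pos]
    kept <- kept + sum(sq == oq)
    raised <- raised + sum(sq > oq)
    lowered <- lowered + sum(sq < oq)
    total <- total + length(pos)
  }
  structure(
    list(error_positions = total, kept = kept, raised = raised,
         lowered = lowered,
         kept_fraction = if (total > 0L) kept / total else NA_real_),
    class = "smoothing_fidelity"
  )
}

#' @export
print.smoothing_fidelity <- function(x, ...) {
  cat(sprintf(
    "<smoothing_fidelity> %d error positions: %d kept, %d raised, %d lowered\n",
    x$error_positions, x$kept, x$raised, x$lowered
  ))
  invisible(x)
}
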