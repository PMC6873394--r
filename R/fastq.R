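# Streaming FASTQ input/output.  Only strict 4-line-per-record FASTQ is
# accepted (wrapped FASTQ is ambiguous to stream deterministically); record
# order is preserved and every non-quality field is written back verbatim.
# Qualities are Phred+33; code points above 'h' (104) strongly suggest
# Phred+64 input and are rejected unless explicitly overridden.

open_text_input <- function(input) {
  if (inherits(input, "connection")) return(list(con = input, owned = FALSE))
  if (identical(input, "-")) {
    return(list(con = file("stdin", open = "r"), owned = TRUE))
  }
  if (!file.exists(input)) format_error(sprintf("input file not found: %s", input))
  # gzfile reads plain files transparently as well
  list(con = gzfile(input, open = "rt"), owned = TRUE)
}

open_text_output <- function(output, gzip = NULL) {
  if (inherits(output, "connection")) return(list(con = output, owned = FALSE))
  if (identical(output, "-")) return(list(con = stdout(), owned = FALSE))
  if (is.null(gzip)) gzip <- grepl("\\.gz$", output)
  con <- if (gzip) gzfile(output, open = "wt") else file(output, open = "wt")
  list(con = con, owned = TRUE)
}

# Validate and assemble one chunk of raw FASTQ lines into a record frame.
# `start_record` gives the 1-based index of the chunk's first record so
# malformed records are reported with their absolute position in the stream.
parse_fastq_lines <- function(lines, start_record = 1L,
                              allow_high_quality = FALSE) {
  nl <- length(lines)
  if (nl %% 4L != 0L) {
    format_error(sprintf(
      "truncated FASTQ: record %d is incomplete (%d trailing line(s))",
      start_record + nl %/% 4L, nl %% 4L
    ))
  }
  if (nl == 0L) {
    return(data.frame(header = character(), sequence = character(),
                      separator = character(), quality = character(),
                      stringsAsFactors = FALSE))
  }
  h <- lines[seq.int(1L, nl, by = 4L)]
  s <- lines[seq.int(2L, nl, by = 4L)]
  p <- lines[seq.int(3L, nl, by = 4L)]
  q <- lines[seq.int(4L, nl, by = 4L)]
  recno <- start_record + seq_along(h) - 1L

  bad <- which(!startsWith(h, "@"))
  if (length(bad)) {
    format_error(sprintf("record %d does not start with '@'", recno[bad[1]]))
  }
  bad <- which(!startsWith(p, "+"))
  if (length(bad)) {
    format_error(sprintf(
      "separator line of record %d does not start with '+'", recno[bad[1]]
    ))
  }
  bad <- which(nchar(s) == 0L)
  if (length(bad)) {
    format_error(sprintf("record %d has an empty sequence", recno[bad[1]]))
  }
  bad <- which(nchar(s) != nchar(q))
  if (length(bad)) {
    format_error(sprintf(
      "sequence/quality length mismatch in record %d (%d vs %d)",
      recno[bad[1]], nchar(s)[bad[1]], nchar(q)[bad[1]]
    ))
  }
  bad <- which(grepl("[^ACGTNacgtn]", s))
  if (length(bad)) {
    format_error(sprintf(
      "invalid sequence character in record %d (only A, C, G, T, N accepted)",
      recno[bad[1]]
    ))
  }
  qb <- as.integer(charToRaw(paste(q, collapse = "")))
  rng <- range(qb)
  if (rng[1] < 33L || rng[2] > 126L) {
    bad <- which(vapply(
      q, function(x) {
        v <- as.integer(charToRaw(x))
        any(v < 33L | v > 126L)
      },
      logical(1), USE.NAMES = FALSE
    ))
    format_error(sprintf(
      "quality character outside the printable Phred+33 range in record %d",
      recno[bad[1]]
    ))
  }
  if (!allow_high_quality && rng[2] > 104L) {
    format_error(paste(
      "quality code points above 104 suggest Phred+64 input;",
      "convert to Phred+33 or set allow_high_quality = TRUE"
    ))
  }
  data.frame(header = substring(h, 2L), sequence = s, separator = p,
             quality = q, stringsAsFactors = FALSE)
}

#' Read a FASTQ file into a record frame
#'
#' @param input path (optionally `.gz`), `"-"` for standard input, or an open
#'   text connection.
#' @param allow_high_quality accept quality code points above 104 (which
#'   normally indicate Phred+64 data).
#' @return a `data.frame` with columns `header` (without the leading `@`),
#'   `sequence`, `separator` (the `+` line verbatim) and `quality`, in file
#'   order.
#' @export
read_fastq <- function(input, allow_high_quality = FALSE) {
  io <- open_text_input(input)
  if (io$owned) on.exit(close(io$con))
  parse_fastq_lines(readLines(io$con, warn = FALSE),
                    allow_high_quality = allow_high_quality)
}

#' Write a record frame as FASTQ
#'
#' Output uses LF newlines regardless of input; headers, sequences and
#' separators are written back byte-for-byte.
#'
#' @param records a record frame as returned by [read_fastq()].
#' @param output path, `"-"` for standard output, or an open text connection.
#' @param gzip force (or suppress) gzip compression; default: by `.gz` suffix.
#' @return the output, invisibly.
#' @export
write_fastq <- function(records, output, gzip = NULL) {
  io <- open_text_output(output, gzip)
  if (io$owned) on.exit(close(io$con))
  n <- nrow(records)
  out <- character(4L * n)
  if (n > 0L) {
    out[seq.int(1L, 4L * n, by = 4L)] <- paste0("@", records$header)
    out[seq.int(2L, 4L * n, by = 4L)] <- records$sequence
    out[seq.int(3L, 4L * n, by = 4L)] <- records$separator
    out[seq.int(4L, 4L * n, by = 4L)] <- records$quality
  }
  writeLines(out, io$con, sep = "\n")
  invisible(output)
}

# Stream records chunk-wise from `input` to `output`, applying `fun` to each
# record frame.  Memory use is bounded by `chunk_size` records, never by the
# file size.  Returns the list of per-chunk values of `attr(result, "extra")`
# if `fun` attaches one (used by the smoother to accumulate its report).
fastq_chunk_apply <- function(input, output, fun, chunk_size = 5000L,
                              allow_high_quality = FALSE, gzip = NULL) {
  ii <- open_text_input(input)
  if (ii$owned) on.exit(close(ii$con), add = TRUE)
  oo <- open_text_output(output, gzip)
  if (oo$owned) on.exit(close(oo$con), add = TRUE)
  extras <- list()
  done <- 0L
  repeat {
    lines <- readLines(ii$con, n = 4L * chunk_size, warn = FALSE)
    if (length(lines) == 0L) break
    recs <- parse_fastq_lines(lines, start_record = done + 1L,
                              allow_high_quality = allow_high_quality)
    res <- fun(recs)
    extra <- attr(res, "extra")
    if (!is.null(extra)) extras[[length(extras) + 1L]] <- extra
    write_fastq(res, oo$con)
    done <- done + nrow(recs)
    if (length(lines) < 4L * chunk_size) break
  }
  invisible(list(records = done, extras = extras))
}
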