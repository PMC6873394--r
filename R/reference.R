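# Reference sequences: the dictionary source for the FM-index.
#
# Internally a reference is one concatenated uppercase string over
# {A,C,G,T,N}.  Multiple FASTA records are joined with a single "N"
# separator (so no all-ACGT k-mer can span two records) and a unique "$"
# terminator is appended; `boundaries` records the 1-based start of each
# input sequence within the concatenation.

#' Construct a reference from nucleotide sequences
#'
#' @param sequences character vector of sequences over `{A,C,G,T,N}`
#'   (case-insensitive).
#' @param names sequence identifiers; defaults to `seq_1`, `seq_2`, ...
#' @return an object of class `fq_reference` with fields `names`, `text`
#'   (concatenation with `N` separators and a trailing `$` terminator) and
#'   `boundaries` (1-based start offsets).
#' @export
#' @examples
#' ref <- fq_reference(c("ACGT", "GGCC"))
#' ref$text
fq_reference <- function(sequences, names = NULL) {
  if (length(sequences) == 0) format_error("reference must contain at least one sequence")
  if (is.null(names)) names <- paste0("seq_", seq_along(sequences))
  if (length(names) != length(sequences)) {
    format_error("names and sequences differ in length")
  }
  sequences <- toupper(sequences)
  for (i in seq_along(sequences)) {
    if (!nzchar(sequences[i])) {
      format_error(sprintf("record '%s' has an empty sequence", names[i]))
    }
    m <- regexpr("[^ACGTN]", sequences[i])
    if (m != -1L) {
      format_error(sprintf(
        "invalid character '%s' in record '%s' (only A, C, G, T, N are accepted)",
        substr(sequences[i], m, m), names[i]
      ))
    }
  }
  lens <- nchar(sequences)
  boundaries <- cumsum(c(1L, head(lens, -1L) + 1L))  # +1 for each N separator
  text <- paste0(paste(sequences, collapse = "N"), TERMINATOR)
  ref <- structure(
    list(names = names, text = text, boundaries = as.integer(boundaries)),
    class = "fq_reference"
  )
  validate_reference(ref)
  ref
}

validate_reference <- function(ref) {
  if (!inherits(ref, "fq_reference")) format_error("not an fq_reference object")
  n <- nchar(ref$text)
  if (n < 2L) format_error("reference text is empty")
  if (substr(ref$text, n, n) != TERMINATOR ||
      grepl("\\$", substr(ref$text, 1L, n - 1L))) {
    format_error("terminator must occur exactly once, at the final position")
  }
  if (!grepl("^[ACGTN]*\\$$", ref$text)) {
    format_error("reference text contains characters outside {A,C,G,T,N}")
  }
  b <- ref$boundaries
  if (length(b) != length(ref$names) || any(diff(b) <= 0L) ||
      b[1] != 1L || b[length(b)] > n - 1L) {
    format_error("reference boundaries are inconsistent")
  }
  invisible(ref)
}

# Split the concatenation back into the original sequences.
ref_sequences <- function(ref) {
  validate_reference(ref)
  n <- nchar(ref$text)
  starts <- ref$boundaries
  ends <- c(starts[-1L] - 2L, n - 1L)  # drop N separators and terminator
  stats::setNames(substring(ref$text, starts, ends), ref$names)
}

#' @export
print.fq_reference <- function(x, ...) {
  cat(sprintf(
    "<fq_reference> %d sequence(s), %d bp total (incl. separators/terminator)\n",
    length(x$names), nchar(x$text)
  ))
  invisible(x)
}

#' Read a reference from a FASTA file
#'
#' Accepts plain or gzip-compressed FASTA with one or more records.
#' Lowercase is uppercased; any letter outside `{A,C,G,T,N}` (including
#' IUPAC ambiguity codes other than N) is rejected with an error naming the
#' character and the record.
#'
#' @param path path to a FASTA file (optionally `.gz`).
#' @return an [fq_reference()] object.
#' @export
read_fasta <- function(path) {
  if (!is.character(path) || !file.exists(path)) {
    format_error(sprintf("FASTA file not found: %s", path))
  }
  x <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) format_error(sprintf("cannot parse FASTA '%s': %s",
                                             path, conditionMessage(e)))
  )
  if (length(x) == 0) format_error(sprintf("empty FASTA file: %s", path))
  fq_reference(as.character(x), names = names(x))
}

#' Write a reference to a FASTA file
#'
#' @param ref an [fq_reference()] object.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param width line-wrap width in bases.
#' @return the path, invisibly.
#' @export
write_fasta <- function(ref, path, width = 70L) {
  seqs <- ref_sequences(ref)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
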