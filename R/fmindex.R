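# FM-index over the reference concatenation: suffix array, BWT, count and
# checkpointed-rank (occ) tables, plus a sampled suffix array.  Membership
# queries (exact or with one substitution, either strand) drive smoothing;
# locate() is never needed, the samples are retained for debugging.

#' Suffix array of a terminated text
#'
#' Sorts all suffixes of `text` in byte order.  The final character must be a
#' unique terminator that sorts strictly before every other symbol.
#'
#' @param text a character scalar ending in a unique, smallest terminator
#'   (e.g. `"$"`).
#' @return integer vector of 0-based suffix start positions in lexicographic
#'   order of the suffixes.
#' @export
#' @examples
#' build_suffix_array("banana$")
build_suffix_array <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text)) {
    format_error("text must be a non-empty character scalar")
  }
  b <- charToRaw(text)
  n <- length(b)
  term <- b[n]
  if (sum(b == term) != 1L) {
    format_error("terminator must occur exactly once, at the final position")
  }
  if (n > 1L && any(b[-n] <= term)) {
    format_error("terminator must sort strictly before all other symbols")
  }
  sa_build_cpp(b)
}

#' Burrows-Wheeler transform from a suffix array
#'
#' `bwt[i] = text[sa[i] - 1]`, with `text[-1]` taken as the final character
#' (the terminator).
#'
#' @param text the terminated text the suffix array was built from.
#' @param suffix_array 0-based suffix array of `text`.
#' @return the BWT as a character scalar of the same length as `text`.
#' @export
#' @examples
#' bwt_from_suffix_array("banana$", build_suffix_array("banana$"))
bwt_from_suffix_array <- function(text, suffix_array) {
  b <- charToRaw(text)
  if (length(suffix_array) != length(b)) {
    format_error("text and suffix array lengths differ")
  }
  rawToChar(bwt_from_sa_cpp(b, as.integer(suffix_array)))
}

#' Invert a Burrows-Wheeler transform
#'
#' Reconstructs the original terminated text by iterating the LF-mapping from
#' the terminator's row.  Intended for verification at small scale.
#'
#' @param bwt a BWT string containing exactly one terminator (its smallest
#'   byte).
#' @return the reconstructed text.
#' @export
#' @examples
#' inverse_bwt("annb$aa")
inverse_bwt <- function(bwt) {
  codes <- as.integer(charToRaw(bwt))
  n <- length(codes)
  if (n == 0) format_error("empty BWT")
  tab <- tabulate(codes, 256L)
  smaller <- c(0L, cumsum(tab))[codes]          # chars strictly smaller
  within <- stats::ave(rep(1L, n), codes, FUN = cumsum) - 1L  # rank among equals
  lf <- smaller + within                        # 0-based destination row
  out <- integer(n)
  i <- 0L                                       # row 0 is the terminator suffix
  for (step in seq_len(n - 1L)) {
    out[n - step] <- codes[i + 1L]
    i <- lf[i + 1L]
  }
  out[n] <- min(codes)  # the terminator is the final character
  intToUtf8(out)
}

#' Build an FM-index over a reference
#'
#' Indexes the forward concatenation only; queries consult the reverse
#' complement of the k-mer instead (see [search_membership()]).  `N` is
#' indexed as a fifth symbol, so no all-ACGT query ever matches a window
#' containing `N`.
#'
#' @param reference an [fq_reference()] object.
#' @param sample_rate suffix-array sampling rate (every `sample_rate`-th row).
#' @param max_length capacity guard for the pure in-memory build, in bases.
#' @return an object of class `fm_index`.
#' @export
build_index <- function(reference, sample_rate = 32L, max_length = 256e6) {
  validate_reference(reference)
  sample_rate <- as.integer(sample_rate)
  if (is.na(sample_rate) || sample_rate < 1L) {
    format_error("sample_rate must be a positive integer")
  }
  n <- nchar(reference$text)
  if (n > max_length) {
    capacity_error(sprintf(
      "reference length %d exceeds the in-memory capacity guard (%g bp)",
      n, max_length
    ))
  }
  raw <- charToRaw(reference$text)
  codes <- .dna_codes[as.integer(raw) + 1L]
  sa <- sa_build_cpp(raw)
  # bwt[i] = code of text[sa[i]-1] (0-based), wrapping sa==0 to the last char;
  # in 1-based R indexing that char sits at position sa[i] (or n after wrap).
  idx <- sa
  idx[idx == 0L] <- n
  bwt <- codes[idx]
  counts <- as.integer(c(0L, cumsum(tabulate(bwt + 1L, 6L)))[1:6])
  occ_step <- 32L
  occ <- occ_build_cpp(bwt, 6L, occ_step)
  sa_samples <- sa[seq.int(1L, n, by = sample_rate)]
  structure(
    list(
      bwt = bwt, counts = counts, occ = occ, occ_step = occ_step,
      sa_samples = as.integer(sa_samples), sample_rate = sample_rate,
      alphabet = DNA_ALPHABET, n = as.integer(n),
      reference_names = reference$names,
      reference_boundaries = reference$boundaries
    ),
    class = "fm_index"
  )
}

#' @export
print.fm_index <- function(x, ...) {
  cat(sprintf(
    "<fm_index> %d bp, alphabet {%s}, SA sample rate %d\n",
    x$n, paste(x$alphabet, collapse = ","), x$sample_rate
  ))
  invisible(x)
}

#' Count exact occurrences of a pattern by backward search
#'
#' @param index an `fm_index`.
#' @param pattern non-empty pattern over `{A,C,G,T}` (case-insensitive).
#'   Patterns containing any other symbol never match and count 0.
#' @return number of occurrences of `pattern` in the indexed concatenation
#'   (forward strand only).
#' @export
backward_search_exact <- function(index, pattern) {
  stopifnot(inherits(index, "fm_index"))
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern)) {
    format_error("pattern must be a non-empty character scalar")
  }
  codes <- encode_dna(toupper(pattern))
  if (!all(codes %in% ACGT_CODES)) return(0L)
  bs_count_cpp(index$bwt, index$occ, index$occ_step, index$counts, codes)
}

#' k-mer membership with up to one mismatch
#'
#' Reports whether `kmer` (or, when `both_strands`, its reverse complement)
#' occurs in the indexed reference within Hamming distance
#' `max_mismatches`, where distance is over ACGT substitutions only (a
#' reference window containing `N` never qualifies).  `concordant_positions`
#' is the union, over all minimum-distance qualifying occurrences, of the
#' 0-based k-mer positions matched without substitution; reverse-complement
#' hits are mirrored back into the original k-mer's coordinates.
#'
#' @param index an `fm_index`.
#' @param kmer query of length >= 2; a k-mer containing non-ACGT characters
#'   is reported as not found (contract, not an error).
#' @param max_mismatches 0 or 1.
#' @param both_strands also query the reverse complement (default `TRUE`).
#' @return an object of class `fm_search_result`: list with `found`, `exact`
#'   and `concordant_positions` (0-based integer vector).
#' @export
search_membership <- function(index, kmer, max_mismatches = 1L,
                              both_strands = TRUE) {
  stopifnot(inherits(index, "fm_index"))
  if (!is.character(kmer) || length(kmer) != 1L || nchar(kmer) < 2L) {
    format_error("kmer must be a character scalar of length >= 2")
  }
  max_mismatches <- as.integer(max_mismatches)
  if (!max_mismatches %in% c(0L, 1L)) {
    format_error("max_mismatches must be 0 or 1")
  }
  codes <- encode_dna(toupper(kmer))
  res <- membership_cpp(index$bwt, index$occ, index$occ_step, index$counts,
                        codes, max_mismatches, isTRUE(both_strands))
  structure(
    list(found = res$found, exact = res$exact,
         concordant_positions = sort(res$concordant)),
    class = "fm_search_result"
  )
}

#' @export
print.fm_search_result <- function(x, ...) {
  cat(sprintf(
    "<fm_search_result> found=%s exact=%s concordant=%s\n",
    x$found, x$exact, paste(x$concordant_positions, collapse = ",")
  ))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Serialization.  Single little-endian binary file:
#   bytes 0-7   magic "FQSMIDX1"
#   int32       format version (1)
#   int32       n (text length)      int32 sample_rate     int32 occ_step
#   int32       nsym, then nsym alphabet bytes
#   int32[nsym] counts
#   int32       n_samples, then int32[n_samples] sa_samples
#   int32       n_names, then per name: int32 length + bytes
#   int32[n_names] boundaries
#   byte[n]     BWT symbol codes
# The occ table is rebuilt on load, so two builds of the same reference are
# byte-identical on disk.

INDEX_MAGIC <- "FQSMIDX1"
INDEX_VERSION <- 1L

#' Save an FM-index to a binary file
#'
#' @param index an `fm_index`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "fm_index"))
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  writeBin(charToRaw(INDEX_MAGIC), con)
  wi(INDEX_VERSION)
  wi(index$n); wi(index$sample_rate); wi(index$occ_step)
  wi(length(index$alphabet))
  writeBin(charToRaw(paste(index$alphabet, collapse = "")), con)
  wi(index$counts)
  wi(length(index$sa_samples)); wi(index$sa_samples)
  wi(length(index$reference_names))
  for (nm in index$reference_names) {
    r <- charToRaw(nm)
    wi(length(r))
    writeBin(r, con)
  }
  wi(index$reference_boundaries)
  writeBin(as.raw(index$bwt), con)
  invisible(path)
}

#' Load an FM-index from a binary file
#'
#' Corrupted, truncated or version-mismatched files raise an explicit index
#' format error; answers after a round trip are identical to the saved
#' index's.
#'
#' @param path path written by [save_index()].
#' @return an `fm_index`.
#' @export
load_index <- function(path) {
  if (!is.character(path) || !file.exists(path)) {
    index_error(sprintf("index file not found: %s", path))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(k = 1L) {
    x <- readBin(con, integer(), k, size = 4L, endian = "little")
    if (length(x) != k) index_error("truncated index file")
    x
  }
  rraw <- function(k) {
    x <- readBin(con, raw(), k)
    if (length(x) != k) index_error("truncated index file")
    x
  }
  magic <- readBin(con, raw(), nchar(INDEX_MAGIC))
  if (!identical(magic, charToRaw(INDEX_MAGIC))) {
    index_error("not an fqsmooth index file (bad magic bytes)")
  }
  version <- ri()
  if (version != INDEX_VERSION) {
    index_error(sprintf("unsupported index format version %d", version))
  }
  n <- ri(); sample_rate <- ri(); occ_step <- ri()
  nsym <- ri()
  if (nsym < 2L || nsym > 16L) index_error("corrupt index: bad alphabet size")
  alphabet <- strsplit(rawToChar(rraw(nsym)), "")[[1]]
  counts <- ri(nsym)
  n_samples <- ri()
  sa_samples <- ri(n_samples)
  n_names <- ri()
  ref_names <- character(n_names)
  for (i in seq_len(n_names)) ref_names[i] <- rawToChar(rraw(ri()))
  boundaries <- ri(n_names)
  bwt <- as.integer(rraw(n))
  if (length(readBin(con, raw(), 1L)) != 0L) {
    index_error("trailing bytes after index payload")
  }
  if (any(bwt >= nsym)) index_error("corrupt index: BWT symbol out of range")
  if (is.unsorted(counts)) index_error("corrupt index: counts not monotone")
  structure(
    list(
      bwt = bwt, counts = counts,
      occ = occ_build_cpp(bwt, nsym, occ_step), occ_step = occ_step,
      sa_samples = sa_samples, sample_rate = sample_rate,
      alphabet = alphabet, n = n,
      reference_names = ref_names, reference_boundaries = boundaries
    ),
    class = "fm_index"
  )
}
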