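# Brute-force oracles, independent of the FM-index implementation: naive
# suffix sorting on byte codes (locale-free), overlapping-occurrence counting
# by regex lookahead, Hamming-neighbor enumeration for one-mismatch
# membership, and a literal rule-by-rule smoother.

ACGT <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(ACGT, n, replace = TRUE), collapse = "")

rc_oracle <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Naive suffix array: order suffixes by comparing padded byte-code rows.
naive_suffix_array <- function(text) {
  b <- as.integer(charToRaw(text))
  n <- length(b)
  m <- matrix(-1L, nrow = n, ncol = n)
  for (i in seq_len(n)) m[i, seq_len(n - i + 1L)] <- b[i:n]
  ord <- do.call(order, lapply(seq_len(n), function(j) m[, j]))
  ord - 1L
}

# Overlapping occurrence count of an exact pattern (lookahead regex).
naive_count <- function(text, pattern) {
  hits <- gregexpr(paste0("(?=", pattern, ")"), text, perl = TRUE)[[1]]
  if (hits[1] == -1L) 0L else length(hits)
}

# Membership within Hamming distance <= maxmm, defined by ACGT neighbor
# enumeration + exact scan (so reference windows containing N never match).
# Returns found/exact and the 0-based concordant positions of the original
# k-mer: the union over minimum-distance occurrences of unsubstituted
# positions.
naive_membership <- function(text, kmer, maxmm = 1L, both_strands = TRUE) {
  m <- nchar(kmer)
  if (grepl("[^ACGT]", kmer)) {
    return(list(found = FALSE, exact = FALSE, concordant = integer(0)))
  }
  queries <- list(list(pat = kmer, mirror = FALSE))
  if (both_strands) {
    queries <- c(queries, list(list(pat = rc_oracle(kmer), mirror = TRUE)))
  }
  exact <- any(vapply(queries, function(qq) naive_count(text, qq$pat) > 0L,
                      logical(1)))
  if (exact) {
    return(list(found = TRUE, exact = TRUE, concordant = 0:(m - 1L)))
  }
  if (maxmm < 1L) {
    return(list(found = FALSE, exact = FALSE, concordant = integer(0)))
  }
  mism <- integer(0)  # positions (original coords) with a 1-mismatch witness
  for (qq in queries) {
    ch <- strsplit(qq$pat, "")[[1]]
    for (j in seq_len(m)) {
      for (sub in setdiff(ACGT, ch[j])) {
        nb <- ch
        nb[j] <- sub
        if (naive_count(text, paste(nb, collapse = "")) > 0L) {
          mism <- union(mism, if (qq$mirror) m - j else j - 1L)
          break
        }
      }
    }
  }
  if (length(mism) == 0L) {
    return(list(found = FALSE, exact = FALSE, concordant = integer(0)))
  }
  conc <- if (length(mism) == 1L) setdiff(0:(m - 1L), mism) else 0:(m - 1L)
  list(found = TRUE, exact = FALSE, concordant = sort(conc))
}

# Literal implementation of the four smoothing rules on one read.
naive_smooth <- function(sequence, quality, text, params) {
  n <- nchar(sequence)
  k <- params$k
  qv <- as.integer(charToRaw(quality)) - params$offset
  bases <- strsplit(toupper(sequence), "")[[1]]
  ok <- qv >= params$lower_threshold & bases %in% ACGT
  W <- n - k + 1L
  queried <- logical(max(W, 0L))
  results <- vector("list", max(W, 0L))
  if (W > 0L) {
    for (w in seq_len(W)) {
      if (all(ok[w:(w + k - 1L)])) {
        queried[w] <- TRUE
        results[[w]] <- naive_membership(
          text, substr(toupper(sequence), w, w + k - 1L),
          params$max_mismatches, params$both_strands
        )
      }
    }
  }
  out <- qv
  for (p in seq_len(n)) {
    if (qv[p] > params$higher_threshold) {
      out[p] <- params$replacement_quality
      next
    }
    if (qv[p] < params$lower_threshold) next
    lo <- max(1L, p - k + 1L)
    hi <- min(p, W)
    covering <- if (W >= 1L && hi >= lo) lo:hi else integer(0)
    covering <- covering[queried[covering]]
    if (length(covering) == 0L) next
    conc_all <- all(vapply(covering, function(w) {
      r <- results[[w]]
      r$found && ((p - w) %in% r$concordant)
    }, logical(1)))
    if (conc_all) out[p] <- params$replacement_quality
  }
  intToUtf8(out + params$offset)
}

make_record <- function(sequence, quality) {
  data.frame(header = "r1", sequence = sequence, separator = "+",
             quality = quality, stringsAsFactors = FALSE)
}

# A reference plus its index, from raw sequence strings.
indexed_ref <- function(...) {
  ref <- fq_reference(c(...))
  list(ref = ref, idx = build_index(ref))
}
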