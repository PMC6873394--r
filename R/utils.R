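# Internal helpers shared across modules.

# Condition constructors; the CLI maps these classes onto exit codes.
format_error <- function(msg) {
  stop(errorCondition(msg, class = c("fqsmooth_format_error", "error")))
}
index_error <- function(msg) {
  stop(errorCondition(msg, class = c("fqsmooth_index_error", "error")))
}
usage_error <- function(msg) {
  stop(errorCondition(msg, class = c("fqsmooth_usage_error", "error")))
}
capacity_error <- function(msg) {
  stop(errorCondition(msg, class = c("fqsmooth_capacity_error", "error")))
}

TERMINATOR <- "$"
DNA_ALPHABET <- c("$", "A", "C", "G", "N", "T")  # ASCII order; codes 0..5
ACGT_CODES <- c(1L, 2L, 3L, 5L)

.dna_codes <- local({
  v <- rep(-1L, 256L)
  v[utf8ToInt("$") + 1L] <- 0L
  v[utf8ToInt("A") + 1L] <- v[utf8ToInt("a") + 1L] <- 1L
  v[utf8ToInt("C") + 1L] <- v[utf8ToInt("c") + 1L] <- 2L
  v[utf8ToInt("G") + 1L] <- v[utf8ToInt("g") + 1L] <- 3L
  v[utf8ToInt("N") + 1L] <- v[utf8ToInt("n") + 1L] <- 4L
  v[utf8ToInt("T") + 1L] <- v[utf8ToInt("t") + 1L] <- 5L
  v
})

# Symbol codes (0-based, -1 for anything outside the indexed alphabet).
encode_dna <- function(x) {
  .dna_codes[as.integer(charToRaw(x)) + 1L]
}

#' Reverse complement of nucleotide strings
#'
#' Vectorised; `N` complements to itself.
#'
#' @param x character vector of sequences over `{A,C,G,T,N}` (case kept).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement("ACGTN")
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Run `expr` under `seed` without clobbering the caller's RNG stream.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  expr
}
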