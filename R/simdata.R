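# Synthetic references and Illumina-like reads with a known-error truth
# channel, so every other module is testable without downloads.  The error
# model is substitution-only (the smoothing rule is Hamming-based; indels
# would only create uncovered windows) and qualities are drawn from two
# user-configurable distributions: one for correct bases, one for erroneous
# bases, the latter concentrated at low Phred values as on real instruments.

#' A discrete distribution over Phred values
#'
#' @param values integer Phred values in `[0, 93]`.
#' @param probs matching probabilities; default uniform.  Normalised to sum
#'   to 1.
#' @return an object of class `phred_dist`.
#' @export
#' @examples
#' phred_dist(30:41)          # uniform over the upper Illumina range
phred_dist <- function(values, probs = NULL) {
  values <- as.integer(values)
  if (length(values) == 0 || any(is.na(values)) ||
      any(values < 0L | values > 93L)) {
    format_error("Phred values must lie in [0, 93]")
  }
  if (is.null(probs)) probs <- rep(1, length(values))
  if (length(probs) != length(values) || any(probs < 0) || sum(probs) <= 0) {
    format_error("probs must be non-negative and match values in length")
  }
  structure(list(values = values, probs = probs / sum(probs)),
            class = "phred_dist")
}

draw_phred <- function(dist, n) {
  dist$values[sample.int(length(dist$values), n, replace = TRUE,
                         prob = dist$probs)]
}

#' Simulation configuration
#'
#' Defaults describe the standard synthetic benchmark used throughout the
#' package: a 100 kb uniform-random reference, 1000 reads of 100 bp, 1%
#' substitution errors, correct bases at Phred 30-41 and erroneous bases at
#' Phred 2-20 (both uniform) so that both thresholds are exercised.
#'
#' @param reference_length reference length in bp.
#' @param n_reads number of reads.
#' @param read_length read length in bp (<= `reference_length`).
#' @param error_rate per-base substitution probability in `[0, 1]`.
#' @param quality_correct,quality_error [phred_dist()] objects for correct
#'   and erroneous bases.
#' @param seed RNG seed; the same seed reproduces the simulation exactly.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(reference_length = 1e5, n_reads = 1000L,
                              read_length = 100L, error_rate = 0.01,
                              quality_correct = phred_dist(30:41),
                              quality_error = phred_dist(2:20),
                              seed = 1L) {
  cfg <- list(
    reference_length = as.integer(reference_length),
    n_reads = as.integer(n_reads), read_length = as.integer(read_length),
    error_rate = error_rate, quality_correct = quality_correct,
    quality_error = quality_error, seed = as.integer(seed)
  )
  if (cfg$error_rate < 0 || cfg$error_rate > 1) {
    format_error("error_rate must lie in [0, 1]")
  }
  if (cfg$read_length < 1L || cfg$read_length > cfg$reference_length) {
    format_error("read_length must be positive and <= reference_length")
  }
  if (cfg$n_reads < 1L) format_error("n_reads must be positive")
  if (!inherits(quality_correct, "phred_dist") ||
      !inherits(quality_error, "phred_dist")) {
    format_error("quality models must be phred_dist objects")
  }
  structure(cfg, class = "simulation_config")
}

#' Generate a uniform-random reference sequence
#'
#' @param length sequence length in bp (>= 1).
#' @param seed RNG seed; identical seeds give identical sequences.
#' @param name sequence identifier.
#' @return an [fq_reference()] with one sequence of i.i.d. uniform ACGT.
#' @export
generate_reference <- function(length, seed = 1L, name = "synthetic_ref") {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) format_error("length must be >= 1")
  s <- with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""
  ))
  fq_reference(s, names = name)
}

#' Simulate Illumina-like reads from a reference
#'
#' Read origins are uniform over all offsets whose window is all-ACGT,
#' strands are uniform, substitutions are i.i.d. at `error_rate` to a
#' uniformly chosen different base, and qualities are drawn from the
#' configured correct/error distributions.  Error positions are reported in
#' read coordinates (after strand orientation).
#'
#' @param reference an [fq_reference()]; must contain at least one all-ACGT
#'   window of `read_length`.
#' @param config a [simulation_config()].
#' @return an object of class `fq_simulation`: list with `records` (a FASTQ
#'   record frame), `truth` (a data.frame with `read_id`, 0-based `offset`,
#'   `strand` and comma-separated 0-based `error_positions`) and `config`.
#' @export
simulate_reads <- function(reference, config = simulation_config()) {
  validate_reference(reference)
  stopifnot(inherits(config, "simulation_config"))
  text <- substr(reference$text, 1L, nchar(reference$text) - 1L)
  n <- nchar(text)
  L <- config$read_length
  if (L > n) format_error("read_length exceeds reference length")
  ok <- encode_dna(text) %in% ACGT_CODES
  cs <- c(0L, cumsum(!ok))
  starts <- which((cs[(L + 1L):(n + 1L)] - cs[1L:(n - L + 1L)]) == 0L)
  if (length(starts) == 0L) {
    format_error("reference has no all-ACGT window of read_length")
  }
  with_seed(config$seed, {
    nr <- config$n_reads
    off <- starts[sample.int(length(starts), nr, replace = TRUE)]
    strand <- sample(c("+", "-"), nr, replace = TRUE)
    seqs <- substring(text, off, off + L - 1L)
    minus <- strand == "-"
    if (any(minus)) seqs[minus] <- reverse_complement(seqs[minus])
    err <- matrix(runif(nr * L) < config$error_rate, nrow = nr)
    n_err <- sum(err)
    qmat <- matrix(draw_phred(config$quality_correct, nr * L), nrow = nr)
    if (n_err > 0L) qmat[err] <- draw_phred(config$quality_error, n_err)
    err_str <- character(nr)
    for (i in which(rowSums(err) > 0L)) {
      pos <- which(err[i, ])
      ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
      for (p in pos) {
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      }
      seqs[i] <- paste(ch, collapse = "")
      err_str[i] <- paste(pos - 1L, collapse = ",")
    }
    quals <- vapply(seq_len(nr),
                    function(i) intToUtf8(qmat[i, ] + 33L), character(1))
    ids <- sprintf("sim_%05d", seq_len(nr))
    records <- data.frame(
      header = paste0(ids, " pos=", off - 1L, " strand=", strand),
      sequence = seqs, separator = "+", quality = quals,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      read_id = ids, offset = off - 1L, strand = strand,
      error_positions = err_str, stringsAsFactors = FALSE
    )
    structure(list(records = records, truth = truth, config = config),
              class = "fq_simulation")
  })
}

#' Write a simulation to disk
#'
#' @param sim an `fq_simulation` from [simulate_reads()].
#' @param fastq_path output FASTQ path (optionally `.gz`).
#' @param truth_path output path for the tab-separated truth table.
#' @return `sim`, invisibly.
#' @export
write_simulation <- function(sim, fastq_path, truth_path) {
  stopifnot(inherits(sim, "fq_simulation"))
  write_fastq(sim$records, fastq_path)
  write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(sim)
}
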