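# The four-rule smoother: fixed scenarios, rule precedence, and equivalence
# with the literal brute-force implementation on random small instances.

qstr <- function(q, n = length(q)) intToUtf8(rep(q, length.out = n) + 33L)

test_that("Phred arithmetic follows 10^(-q/10)", {
  expect_equal(round(phred_error_probability(6), 5), 0.25119)
  expect_equal(phred_error_probability(0), 1)
  expect_equal(phred_error_probability(40), 1e-4)
  expect_error(phred_error_probability(-1), class = "fqsmooth_format_error")
  expect_error(phred_error_probability(94), class = "fqsmooth_format_error")
})

test_that("smoothing parameter validation enforces the invariants", {
  p <- smoothing_params()
  expect_equal(p$k, 32L)
  expect_equal(p$lower_threshold, 6L)
  expect_equal(p$higher_threshold, 40L)
  expect_equal(p$replacement_quality, 40L)
  expect_error(smoothing_params(k = 1), class = "fqsmooth_format_error")
  expect_error(smoothing_params(lower_threshold = 10, higher_threshold = 5),
               class = "fqsmooth_format_error")
  expect_error(smoothing_params(max_mismatches = 2),
               class = "fqsmooth_format_error")
  expect_error(smoothing_params(replacement_quality = 94),
               class = "fqsmooth_format_error")
})

test_that("a low-quality base disqualifies every covering k-mer", {
  params <- smoothing_params(k = 4, lower_threshold = 6)
  q <- rep(30L, 10)
  q[6] <- 2L  # 0-based position 5
  rec <- make_record(random_dna(10), qstr(q))
  mask <- queried_kmer_mask(rec, params)
  expect_length(mask, 7L)
  expect_equal(which(mask), c(1L, 2L, 7L))  # 0-based starts 0, 1, 6
  # all clean -> all queried; short read -> empty mask
  rec2 <- make_record(random_dna(10), qstr(rep(30L, 10)))
  expect_true(all(queried_kmer_mask(rec2, params)))
  rec3 <- make_record("ACG", "III")
  expect_length(queried_kmer_mask(rec3, smoothing_params(k = 4)), 0L)
})

test_that("a low-quality read tail is trimmed (trailing k-mers skipped)", {
  params <- smoothing_params(k = 4, lower_threshold = 6)
  q <- c(rep(30L, 5), rep(2L, 5))
  rec <- make_record(random_dna(10), qstr(q))
  expect_equal(which(queried_kmer_mask(rec, params)), c(1L, 2L))
  out <- smooth_read(rec, build_index(generate_reference(500, seed = 2)),
                     params)
  expect_equal(substr(out$record$quality, 6, 10), substr(rec$quality, 6, 10))
})

test_that("k-mers containing N are never queried", {
  params <- smoothing_params(k = 4, lower_threshold = 0)
  s <- "ACGTNACGTA"
  rec <- make_record(s, qstr(rep(30L, 10)))
  mask <- queried_kmer_mask(rec, params)
  expect_equal(which(mask), c(1L, 6L, 7L))  # windows overlapping the N skipped
})

test_that("a read fully contained in the reference is fully smoothed", {
  ref <- generate_reference(2000, seed = 31)
  idx <- build_index(ref)
  params <- smoothing_params(k = 8)
  seq <- substr(ref$text, 101, 150)
  rec <- make_record(seq, qstr(rep(30L, 50)))
  out <- smooth_read(rec, idx, params)
  expect_equal(out$record$quality, qstr(rep(40L, 50)))
  expect_true(all(out$labels == "smoothed"))
  expect_identical(out$record$sequence, seq)
})

test_that("a single substitution keeps its own quality, neighbors smoothed", {
  # Fig-1-style scenario with m=0: every window covering the mismatch fails,
  # so qualities within k-1 of it stay; positions covered by a clean window
  # are smoothed.
  ref <- generate_reference(2000, seed = 32)
  idx <- build_index(ref)
  k <- 8L
  params <- smoothing_params(k = k, max_mismatches = 0)
  seq <- substr(ref$text, 501, 550)
  ch <- strsplit(seq, "")[[1]]
  p <- 25L  # 1-based error position, away from the edges
  ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  rec <- make_record(paste(ch, collapse = ""), qstr(rep(30L, 50)))
  out <- smooth_read(rec, idx, params)
  qv <- as.integer(charToRaw(out$record$quality)) - 33L
  expect_equal(qv[p], 30L)
  touched <- (p - k + 1):(p + k - 1)
  expect_true(all(qv[setdiff(seq_len(50), touched)] == 40L))
  # with one mismatch allowed, only the substituted base itself is kept
  out1 <- smooth_read(rec, idx, smoothing_params(k = k, max_mismatches = 1))
  qv1 <- as.integer(charToRaw(out1$record$quality)) - 33L
  expect_equal(which(qv1 == 30L), p)
})

test_that("an unrelated dictionary with maximal H.T. leaves the read intact", {
  # poly-G reads (and their poly-C complements) never occur in an AC repeat
  idx <- build_index(fq_reference(strrep("AC", 250)))
  params <- smoothing_params(k = 8, higher_threshold = 93)
  rec <- make_record(strrep("G", 50), qstr(rep(35L, 50)))
  out <- smooth_read(rec, idx, params)
  expect_identical(out$record$quality, rec$quality)
  expect_true(all(out$labels == "kept_discordant"))
})

test_that("the fast path replaces high qualities without any search", {
  idx <- build_index(fq_reference(strrep("AC", 250)))  # poly-G never found
  params <- smoothing_params(k = 8, higher_threshold = 40)
  q <- rep(c(41L, 35L), 25)
  rec <- make_record(strrep("G", 50), qstr(q))
  out <- smooth_read(rec, idx, params)
  qv <- as.integer(charToRaw(out$record$quality)) - 33L
  expect_equal(qv[q == 41L], rep(40L, 25))       # rule 1 fired
  expect_equal(qv[q == 35L], rep(35L, 25))       # rule 4 kept (discordant)
  expect_equal(unique(out$labels[q == 41L]), "fastpath")
})

test_that("smooth_read equals the literal rule-by-rule brute force", {
  set.seed(77)
  for (i in 1:200) {
    ref <- fq_reference(random_dna(sample(50:200, 1)))
    idx <- build_index(ref)
    k <- sample(3:8, 1)
    params <- smoothing_params(
      k = k,
      max_mismatches = sample(0:1, 1),
      lower_threshold = sample(0:10, 1),
      higher_threshold = sample(30:45, 1),
      both_strands = sample(c(TRUE, FALSE), 1)
    )
    n <- sample(5:50, 1)
    seq <- if (i %% 4 == 0) {
      # read drawn from the reference with sprinkled errors: exercises rule 4
      start <- sample(nchar(ref$text) - n, 1)
      s <- strsplit(substr(ref$text, start, start + n - 1L), "")[[1]]
      ne <- sample(0:2, 1)
      for (p in sample(n, ne)) s[p] <- sample(setdiff(ACGT, s[p]), 1)
      paste(s, collapse = "")
    } else {
      random_dna(n)
    }
    if (i %% 10 == 0) {
      s <- strsplit(seq, "")[[1]]
      s[sample(n, 1)] <- "N"
      seq <- paste(s, collapse = "")
    }
    qual <- qstr(sample(0:50, n, replace = TRUE))
    got <- smooth_read(make_record(seq, qual), idx, params)
    want <- naive_smooth(seq, qual, ref$text, params)
    expect_identical(got$record$quality, want,
                     info = paste(ref$text, seq, qual, k))
  }
})

test_that("smoothing invariants hold on random instances", {
  set.seed(88)
  ref <- generate_reference(5000, seed = 88)
  idx <- build_index(ref)
  params <- smoothing_params(k = 8)
  repl_char <- intToUtf8(params$replacement_quality + params$offset)
  for (i in 1:30) {
    n <- sample(20:80, 1)
    start <- sample(4000, 1)
    seq <- substr(ref$text, start, start + n - 1L)
    qual <- qstr(sample(0:50, n, replace = TRUE))
    rec <- make_record(seq, qual)
    out <- smooth_read(rec, idx, params)
    # output quality alphabet within input alphabet plus the replacement
    in_chars <- unique(strsplit(qual, "")[[1]])
    out_chars <- unique(strsplit(out$record$quality, "")[[1]])
    expect_true(all(out_chars %in% c(in_chars, repl_char)))
    # untouchability below the lower threshold
    qv_in <- as.integer(charToRaw(qual)) - 33L
    qv_out <- as.integer(charToRaw(out$record$quality)) - 33L
    low <- qv_in < params$lower_threshold
    expect_equal(qv_out[low], qv_in[low])
    # sequence bytes unchanged
    expect_identical(out$record$sequence, seq)
    # raising the lower threshold never queries more k-mers
    m1 <- sum(queried_kmer_mask(rec, smoothing_params(k = 8,
                                                      lower_threshold = 6)))
    m2 <- sum(queried_kmer_mask(rec, smoothing_params(k = 8,
                                                      lower_threshold = 20)))
    expect_lte(m2, m1)
  }
})

test_that("stream smoothing preserves order and the counter partition", {
  ref <- generate_reference(20000, seed = 55)
  idx <- build_index(ref)
  sim <- simulate_reads(ref, simulation_config(
    reference_length = 20000, n_reads = 200, read_length = 60,
    error_rate = 0.02, seed = 55
  ))
  res <- smooth_stream(sim$records, idx, smoothing_params(k = 16))
  expect_equal(res$records$header, sim$records$header)
  expect_identical(res$records$sequence, sim$records$sequence)
  r <- res$report
  expect_equal(r$reads_processed, 200)
  expect_equal(
    r$bases_smoothed + r$bases_kept_low_quality + r$bases_kept_discordant +
      r$bases_kept_uncovered + r$bases_fastpathed,
    r$bases_total
  )
  expect_lte(r$kmers_found, r$kmers_queried)
  expect_equal(r$kmers_queried + r$kmers_skipped, 200 * (60 - 16 + 1))
})

test_that("identity configuration returns a byte-identical FASTQ", {
  # empty dictionary (unrelated reference) + H.T. = 93: rules 1/4 never fire
  ref <- generate_reference(3000, seed = 66)
  sim <- simulate_reads(ref, simulation_config(
    reference_length = 3000, n_reads = 100, read_length = 80, seed = 66
  ))
  other <- build_index(fq_reference(strrep("AT", 500)))
  input <- withr::local_tempfile(fileext = ".fastq")
  output <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sim$records, input)
  rep <- smooth_fastq(input, output, other,
                      smoothing_params(higher_threshold = 93),
                      chunk_size = 23L, quiet = TRUE)
  expect_identical(readLines(output), readLines(input))
  expect_equal(rep$bases_smoothed + rep$bases_fastpathed, 0)
  expect_equal(rep$reads_processed, 100)
})
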