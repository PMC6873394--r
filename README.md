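# fqsmooth

Reference-based lossy smoothing of FASTQ quality scores.

Most of the entropy in a FASTQ file lives in its quality string, and much of
that diversity carries no information: when the sequence context around a
base agrees with a reference genome, the base is almost certainly correct
and its exact quality value is noise. `fqsmooth` exploits this: it builds an
FM-index — the Burrows–Wheeler transform of the reference plus count and
rank tables — and uses backward search to ask, for every k-mer of every
read, whether that k-mer occurs in the reference with at most one mismatch.
A base whose covering k-mers are *all* found and concordant gets its quality
replaced by a single high value (Phred 40, `'I'`); every other base keeps
its original quality. The smoothed file compresses far better under
ordinary lossless compressors, while suspect bases — mismatches, low-quality
calls, uncovered read tails — are left untouched for downstream analyses
such as variant calling.

The audience is anyone storing or sharing Illumina-style read sets who
wants substantially smaller files without discarding the quality signal at
exactly the positions where it matters.

## The smoothing rule

For a read of length *n*, k-mer length *k* (default 32), lower threshold
L.T. (default 6), higher threshold H.T. (default 40) and replacement value
Q\* (default 40), each base *p* is handled by the first matching rule:

1. **fast path** — if q(p) > H.T., write Q\* without any search;
2. **low keep** — if q(p) < L.T., keep q(p) unchanged;
3. **uncovered keep** — if no queried k-mer covers *p*, keep q(p).
   A k-mer is queried only when every base it covers has q ≥ L.T. and an
   A/C/G/T call, so one bad base disqualifies all windows covering it and
   low-quality read tails are effectively trimmed from the search;
4. **concordance** — if every queried k-mer covering *p* is found in the
   reference (up to one substitution, either strand) *and* *p* is
   concordant in each hit, write Q\*; otherwise keep q(p).

A k-mer found only with one substitution still counts as found, but the
substituted position is non-concordant: one mismatching base keeps its own
quality untouchable while its neighbours can still be smoothed.

Membership queries run over an FM-index of the reference concatenation
(multi-FASTA records joined by `N`, which never matches an ACGT query), so
the whole dictionary of reference k-mers is stored in linear space with no
explicit k-mer list.

## Worked example

```r
library(fqsmooth)

ref <- generate_reference(1e5, seed = 11)          # 100 kb random reference
idx <- build_index(ref)                             # FM-index
sim <- simulate_reads(ref, simulation_config(       # 1000 x 100 bp reads,
  reference_length = 1e5, n_reads = 1000,           # 1% substitution errors
  read_length = 100, error_rate = 0.01, seed = 11))

res <- smooth_stream(sim$records, idx, smoothing_params())
res$report
#> smoothing report
#>   reads_processed          1000
#>   bases_total              1e+05
#>   bases_smoothed           84427
#>   bases_kept_low_quality   205
#>   bases_kept_discordant    5085
#>   bases_kept_uncovered     2025
#>   bases_fastpathed         8258
#>   kmers_queried            64560
#>   kmers_skipped            4440
#>   kmers_found              62908
```

84.4% of bases were concordant with the reference and had their quality
replaced; 8.3% were already above H.T. and fast-pathed to the same value;
the rest — bases near the 1% simulated errors (`kept_discordant`), below
L.T. (`kept_low_quality`) or covered by no queried k-mer
(`kept_uncovered`) — keep their original qualities. The quality stream's
order-0 entropy drops accordingly:

```r
quality_entropy(sim$records)   # 3.673 bits per symbol
quality_entropy(res$records)   # 0.627 bits per symbol
```

The same pipeline is available from the shell
(`inst/scripts/fqsmooth`), streaming FASTQ through pipes with gzip handled
transparently and the report kept off standard output:

```sh
fqsmooth index ref.fa -o ref.idx
fqsmooth smooth -x ref.idx < reads.fastq > smoothed.fastq
fqsmooth eval --original reads.fastq --smoothed smoothed.fastq
```

## Scope

`fqsmooth` performs membership queries only (no locate or alignment
output), accepts strict 4-line Phred+33 FASTQ, and targets desk-scale
references (an in-memory build with a 256 Mbp capacity guard). See the
vignette in `vignettes/` for the model, parameter guidance and known
limitations.
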