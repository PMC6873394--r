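---
title: "Reference-based quality smoothing with an FM-index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-based quality smoothing with an FM-index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A FASTQ quality value encodes the base-caller's error probability,
$P = 10^{-Q/10}$. Across a read set these values are highly diversified, and
after lossless compression they dominate the file size. Yet for most bases
the exact value is redundant: if the local sequence context of a base —
every k-mer covering it — occurs in a reference genome, the base is almost
certainly a correct call, and a single constant "high confidence" value
loses nothing that downstream analyses use. `fqsmooth` therefore treats the
reference genome as a dictionary of k-mers, represented not as an explicit
list but as an FM-index: the Burrows–Wheeler transform (BWT) of the
reference concatenation together with per-symbol counts and a checkpointed
rank (occurrence) table. Backward search answers "does this k-mer occur?"
in $O(k)$ rank operations without ever materialising the k-mer set, which
is what makes a whole-genome dictionary fit in linear space.

Queries tolerate up to one substitution. The search first attempts an
exact backward match of the k-mer and of its reverse complement (reads come
from either strand; the index stores only the forward concatenation). If
neither is present, the search branches: for each position $j$, the
interval of the exactly-matched suffix right of $j$ is extended with each
of the three alternative bases and then with the remaining prefix. A
position with a surviving interval witnesses a 1-mismatch occurrence
substituted at $j$. Hamming distance is defined over ACGT substitutions
only, so a reference window containing `N` (including the `N` separator
joining multi-FASTA records) never qualifies at any distance — membership
is exactly "some ACGT neighbor at distance ≤ 1 occurs exactly".

**Concordance.** A hit found with one substitution is still a hit, but the
substituted position is suspect. The search result carries the set of
*concordant* positions: the union, over all minimum-distance qualifying
occurrences, of positions matched without substitution. With an exact hit
that is every position; with only 1-mismatch hits, a position is excluded
only when *every* occurrence substitutes there (for single-substitution
hits, when all witnesses agree on the mismatch position). Reverse-strand
hits have their positions mirrored back into the k-mer's own coordinates.

## The smoothing rules and their precedence

Per base, the first matching rule wins; the ordering is fixed and pinned by
tests:

1. *fast path*: quality strictly above the higher threshold H.T. is
   replaced by the replacement value with no search. This is the
   bulk-speedup rule; because it is defined per base it composes
   deterministically with the rules below, and a whole-read shortcut (skip
   all searches when every base exceeds H.T.) would be a pure optimisation
   with identical output.
2. *low keep*: quality strictly below the lower threshold L.T. is never
   modified.
3. *uncovered keep*: bases covered by no queried k-mer keep their quality.
   A k-mer is queried only when all of its bases have quality ≥ L.T. and an
   A/C/G/T call; a single very low quality base therefore disqualifies all
   k-mers covering it, and a low-quality read tail is left entirely
   untouched — the thresholds double as a trimming mechanism.
4. *concordance*: if every queried covering k-mer is found and the base is
   concordant in each, the quality becomes the replacement value;
   otherwise it is kept (discordant).

Both threshold comparisons are strict ("below" L.T., "above" H.T.), and
since L.T. ≤ H.T. is enforced, rules 1 and 2 can never compete for the same
base. Read bases called `N` are never part of a queried k-mer and fall
through to rules 2/3.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 32 | k-mer length. Long enough that the $4^k$ possible k-mers vastly outnumber the reference's, making chance collisions negligible; short enough that most k-mers of an Illumina read contain at most one error. |
| `max_mismatches` | 1 | substitutions tolerated per dictionary hit (0 or 1). |
| `lower_threshold` | 6 | Phred L.T.; $Q=6$ corresponds to error probability $10^{-0.6} \approx 0.251$, i.e. roughly one error in four — bases this unreliable should neither be trusted as context nor have their warning label rewritten. |
| `higher_threshold` | 40 | Phred H.T.; the top of the usual Illumina 0–41 range, so by default only the very best calls skip the search. Lowering it trades fidelity for speed. |
| `replacement_quality` | 40 | the constant written at smoothed positions (`'I'` at Phred+33). Chosen as the top of the Illumina range: "high probability of being correct". |
| `offset` | 33 | quality encoding offset; Phred+64 input is detected heuristically (code points above 104) and rejected unless overridden. |
| `both_strands` | TRUE | also query each k-mer's reverse complement. The index stores the forward concatenation only; querying both orientations gives standard read-versus-reference semantics. |

## Numerical and design choices

* **Suffix array construction** uses prefix doubling ($O(n \log^2 n)$),
  entirely adequate for the desk-scale references this package targets; a
  capacity guard (default 256 Mbp) rejects inputs beyond the in-memory
  design point. The rank structure checkpoints counts every 32 BWT
  positions and scans in between.
* **Serialization** is a single little-endian binary layout with magic
  bytes and a format version; the occurrence table is rebuilt on load, so
  two builds of the same reference are byte-identical on disk. Truncated or
  corrupted files raise explicit index-format errors rather than
  misreading.
* **Multi-record FASTA** is concatenated with an `N` separator. `N` is
  indexed as a fifth symbol (deterministic, never randomised), so no
  ACGT query can match across a record boundary.
* **FASTQ** is strict 4-line Phred+33; records stream in bounded-memory
  chunks, output order always equals input order (which is what keeps
  paired files row-aligned when processed independently), headers,
  sequences and separator lines are reproduced byte-for-byte, and output
  newlines are LF.
* **Ties and degenerate inputs**: reads shorter than `k` have no queried
  k-mers and pass through unchanged apart from the fast path; an empty
  mask, not an error. A k-mer query containing non-ACGT characters reports
  "not found" by contract rather than raising.

## The synthetic benchmark

The simulator emulates an Illumina-like single-end read set at the scale
used throughout the tests: a uniform-random reference (default 100 kb),
1000 reads of 100 bp with uniform origins and strands, i.i.d. substitution
errors (default 1%) to a uniformly chosen different base, correct-base
qualities uniform on Phred 30–41 and error-base qualities uniform on
Phred 2–20 — the two distributions deliberately straddle both thresholds.
A truth table records each read's origin, strand and error positions, so
error-preservation can be checked position by position.

What the simulator does *not* model: indels (the smoothing rule is
Hamming-based; an indel would merely render windows discordant), quality-by-
cycle profiles, PCR duplicates, paired-end insert sizes, or a biological
(repeat-laden) reference. Passing tests therefore demonstrate the
algorithm's correctness and its entropy/compression behaviour under clean
substitution noise, not genotyping performance on real human data; on real
genomes the repeat structure increases one-mismatch hit rates and the
benefit of the reference dictionary depends on how well it matches the
sample.

Problem sizes in the test suite (references of 50–200 bp with k ≤ 8 for
the brute-force equivalence suites, 10–100 kb for end-to-end runs) were
chosen so that exhaustive oracles — naive suffix sorting, neighbor
enumeration with literal rule application — remain tractable while still
exercising every rule and branch.

## Known limitations

* Membership only: no locate, alignment, seed-and-extend or gapped
  matching, and no 2-mismatch search.
* The in-memory index targets desk-scale references; whole-mammalian-genome
  indexing is outside the design point of this implementation.
* Phred+64 input must be converted by the user (the reader only detects and
  refuses it).
* Single-threaded; record-order preservation is the contract that would
  make parallelisation safe, but no thread support is provided.
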