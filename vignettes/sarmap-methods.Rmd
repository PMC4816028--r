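---
title: "Suffix-array seed-and-extend read mapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Suffix-array seed-and-extend read mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The mapping model

`sarmap` maps single-end DNA reads to a reference genome with a three-stage
seed-and-extend pipeline built on an uncompressed suffix array (SA).

**Indexing.** The chromosomes are concatenated with a sentinel character
(`$`, lexicographically below every nucleotide) after each one, so no
suffix comparison or exact match can cross a chromosome boundary. The SA
holds the start offsets of every non-sentinel suffix, ordered by suffix
rank; exact pattern search is binary search over this array. To skip the
first levels of that binary search, a *prefix table* maps every length-$k$
nucleotide string ($k = 18$ by default) that actually occurs at a suffix
start to its half-open interval of SA ranks. Because $4^{18}$ entries
vastly exceed memory, only occurring prefixes are stored — a sorted key
vector (2-bit-packed $k$-mers) plus parallel interval arrays, i.e. a
compressed row storage. A pattern of length $\ge k$ is located with one
binary search over the keys followed by a binary search *within* the
interval; shorter patterns fall back to plain SA search. Suffixes shorter
than $k$, or with an `N` in their first $k$ bases, get no table entry:
seeds are pure-nucleotide strings and `N` never participates in exact
matching.

**Seeding.** Each read of length $L$ is split into $n$ seeds of length $s$
placed uniformly: start offsets $\mathrm{round}(i\,(L-s)/(n-1))$,
$i = 0..n-1$, deduplicated, so the first seed starts at the first base and
the last ends at the last base. Rounding is round-half-to-even, fixed so
seed placement is bit-reproducible. Each seed is searched exactly on the
forward strand, and the corresponding seeds of the reverse-complemented
read give reverse-strand hits — only the forward strand is indexed, which
halves index memory and is standard practice. Seeds with more than
`max_hits_per_seed` occurrences (default 100) are discarded outright:
repeat-saturated seeds carry almost no positional information and would
dominate the work.

**Extension and clustering.** Every seed hit is extended gap-free in both
directions under a shared mismatch budget: alternately one base leftward
then one base rightward (left first, exhausted directions skipped); a
compared pair that differs or involves `N` counts one mismatch, and a
direction stops when accepting its next base would exceed the budget or a
read/chromosome boundary is reached. The alternation order is fixed so
budget consumption — and therefore the whole pipeline — is deterministic.
Extensions are grouped per (chromosome, strand), sorted by genomic start,
and chained into *candidate alignment locations* (CALs) whenever
consecutive extensions are within `max_gap` bases and their diagonals
(genomic start minus read start) differ by at most `max_gap`; a larger
diagonal shift would imply an indel bigger than the cluster is meant to
represent, and starts a new CAL. CALs with a genomic envelope shorter than
`min_cal_length` are dropped. CALs are ranked by how much of the read
their members cover (ties: fewer member mismatches, leftmost coordinate,
forward strand) and the best `max_cals` proceed.

**Gap completion.** Within a selected CAL the member extensions are
chained left-to-right into non-overlapping anchors (overlapping spans on
the same diagonal merge; conflicting ones are dropped — the alignment over
the gap recovers them). Anchors become match/mismatch runs. Each
inter-anchor gap is aligned with an affine-gap dynamic program; read ends
are aligned with an anchored, free-end variant of the same DP against a
reference window of the end's length plus a 10-base indel margin, and any
read prefix/suffix the extension does not align becomes a soft clip. The
internal gaps use the *global* form of the DP rather than the local one
deliberately: read bases between two anchors must all be consumed (a soft
clip cannot occur mid-read), so a local alignment that abandoned part of
the segment would produce an invalid CIGAR. The classic free-start,
free-end local form is exposed as `smith_waterman()` and is what the
end-extension and test oracles exercise. Traceback ties prefer diagonal,
then deletion, then insertion, from the rightmost maximal cell — again for
determinism. The CAL score is

$$\mathrm{score} = m\cdot\#\mathrm{matches} - x\cdot\#\mathrm{mismatches}
  - g_o\cdot\#\mathrm{gap\ runs} - g_e\cdot\#\mathrm{gapped\ bases}$$

with defaults $m = 5$, $x = 4$, $g_o = 10$, $g_e = 0.5$ (classic local
alignment defaults; all four are user flags — the method treats them as
user-defined penalties). The best-scoring CAL alignment is reported (ties:
chromosome order, coordinate, forward strand) with mapping quality
$\min(60, \mathrm{round}(60\,(s_1 - s_2)/s_1))$ from the best and
second-best scores, 60 when a single candidate exists and 0 on an exact
tie. This MAPQ formula is pragmatic plumbing, not part of the underlying
method, and is documented as such.

# Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `k` / prefix length | 18 | bases | prefix-table depth; also default seed length, so each seed search starts with one table probe |
| `num_seeds` | `max(5, floor(L/s))` | seeds | uniform seed count; long reads get proportionally more seeds |
| `max_hits_per_seed` | 100 | hits | repeat cap; bounds worst-case work |
| `max_mismatches` | `ceil(0.04 L)` | mismatches | extension budget, scales with read length |
| `max_gap` | `2 L` | bases | cluster distance and diagonal tolerance; must admit indels and unseeded stretches while staying local |
| `min_cal_length` | `0.25 L` | bases | minimum CAL envelope ("longer than a threshold") |
| `max_cals` | 5 | CALs | bounds DP work; also feeds best-vs-second-best MAPQ |
| `match/mismatch/gap_open/gap_extend` | 5/4/10/0.5 | score | affine scheme; gap of length $l$ costs $g_o + l\,g_e$ |

The length-scaled defaults for the extension budget, cluster gap and CAL
threshold are this package's explicit choices: the underlying method
publishes the pipeline structure but not these constants. All are exposed
as function arguments and CLI flags.

# The read simulator

`simulate_genome()` draws an i.i.d. uniform A/C/G/T sequence — a
deliberately featureless reference. `simulate_reads()` follows the dwgsim
"Illumina" protocol: a read starts at a uniform position and strand; each
output base mutates with probability `mut_rate` (defaults 0.001 or 0.01 as
the two standard noise settings); a mutation is an indel with probability
`indel_frac` = 0.1 (insertion/deletion equiprobable, geometric run length
with continuation `indel_ext` = 0.30, mean $1/(1-0.30)$), otherwise a
substitution to a different base. Sequencer errors are then applied at
`err_rate` = 0.020 per base and marked as Q10 in the otherwise-Q40 quality
string; reads with more than `max_n` = 2 `N`s are redrawn. Mutations are
applied before errors (the simulator the protocol comes from does not
document its internal order; this order is fixed and stated here).
Reverse-strand reads are generated by reverse-complementing a forward
walk, so the truth record always stores the leftmost reference base
consumed — exactly what a SAM `POS` field should reproduce. The origin is
encoded in the read name as `rd_<chrom>_<start>_<strand>_<serial>` and
parsed back by `parse_truth_names()`.

Two honest limitations. First, read start positions keep a 100-base
fragment buffer from the chromosome end so deletion runs cannot exhaust
the source fragment; on megabase chromosomes the resulting edge bias is
negligible. Second, and more importantly, a uniform genome has essentially
no repeats, segmental duplications or low-complexity tracts, which are
the main causes of mapping error on real genomes. Accuracy measured here
therefore *upper-bounds* accuracy on a real reference; passing the bundled
thresholds demonstrates the pipeline's correctness, not its field
performance on human data.

# Evaluation rules

`evaluate_mappings()` implements the two standard correctness rules for
simulated reads: `position_pm5` — reported chromosome, strand and leftmost
position within ±5 bp of the true origin; and `coverage80` — additionally,
at least 80% of the read's bases aligned (`M` operations), the usual guard
against degenerate long-read alignments that align a few dozen bases and
call the rest deletions. Unmapped reads are tallied separately and the
three percentages are reported to two decimals.

# Numerical and degenerate-input choices

* Suffix comparison is plain byte order with the sentinel smallest; the
  construction sorts with `std::sort` and a direct suffix comparator
  (correctness is defined solely by the sortedness postcondition; expected
  $O(n\log n)$ on genomic text, which is all the desk-scale problem sizes
  need).
* DP matrices are doubles; traceback re-derives decisions by exact value
  comparison, which is safe because identical operations are replayed.
* A CAL whose completed alignment has no `M` bases (or fails read-base
  conservation) is discarded; a read whose every CAL is discarded, whose
  seeds are all suppressed, or which finds no seed hit is reported
  unmapped, never dropped.
* Boundary normalization guarantees emitted CIGARs never carry `I`/`D`
  adjacent to a soft clip or record edge; leading deletions shift `POS`
  instead.
* `N` in either read or reference always scores as mismatch, in extension
  and in the DP alike.
* Empty inputs (zero reads, empty FASTQ files) produce a valid SAM with
  headers and zero records.

# Reproducibility contracts

Identical inputs give byte-identical outputs: index files, seed placement,
extension, clustering order, DP traceback and SAM bodies are all
deterministic, and `map_reads()` output is invariant to `batch_size` and
`workers` (batches are reassembled in input order; parallelism is a
throughput device only, replacing the SIMD/multicore engineering of the
original implementation with a determinism contract). The test suite
checks worker-count invariance byte-for-byte on SAM output.

# Problem sizes used in the bundled checks

The end-to-end checks simulate a 1 Mb two-chromosome genome with 10 000
reads at each length in {100, 400, 800} under the high-quality noise
settings, plus a noise-free control; oracle sweeps use 1 000 random
search cases, 1 000 random alignment pairs (≤ 200 bp) against an
independent affine-gap implementation, and 500 random extension walks.
These sizes keep the whole suite in the one-to-two-minute range on a
single core while leaving the accuracy margins wide (measured minimum
correctness across lengths is ≈ 99.6–99.7%, against a 98% threshold).

# Known limitations

Single-end mapping only; one primary alignment per read (no secondary or
chimeric records); no re-seeding of uncovered read regions; no
quality-aware scoring; the indel-realignment and base-quality-recalibration
post-processing stages of the original tool are out of scope, as are
FM-index/BWT-style compressed indexes.
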