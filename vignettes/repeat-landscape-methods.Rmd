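---
title: "Methods: repeat landscapes from low-coverage WGS reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat landscapes from low-coverage WGS reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `repeatscape`. The package targets a specific situation:
a genome far too large and repeat-rich to assemble, a handful of
reference contigs (BAC-scale windows into the genome), and a pool of
short fixed-length WGS reads at a small fraction of 1× coverage. The
statistics below all rest on one observation — at coverage `c` each
single-copy locus is covered by `c` read-equivalents in expectation,
while a family with `k` dispersed copies stacks `k · c` read-equivalents
onto any one of its loci.

## Alignment model

Reads are aligned locally with match +1, mismatch −1, and a linear gap
cost of 2 per gap column (gap open equals gap extension). Stringency is
expressed as a minimum nucleotide identity over the alignment columns
(defaults 0.75 and 0.99); raw score thresholds are available as a
compatibility mode. Note that under this scoring a full-length ungapped
60 bp alignment scoring 55 implies at worst 96.7% identity and one
scoring 24 implies 70% — score thresholds and round identity levels do
not map onto each other exactly, which is why both modes exist
(`identity_for_score()` makes the conversion explicit).

The production aligner is seeded: exact words shared between read and
contig propose diagonal windows, and a full local dynamic program is run
inside each window, iteratively extracting non-overlapping alignments.
The word size is 11 for searches at ≥ 0.95 identity and 8 otherwise. An
8-mer seed is guaranteed to exist for any full-length 60 bp alignment
with at most six mismatches; beyond that the seed is probabilistic, and
sensitivity decays once read-to-contig divergence exceeds roughly 15%.
The package ships a deliberately independent full Smith–Waterman oracle
(`sw_oracle()`, full-matrix, iterative extraction with contig-footprint
blocking) used by the test suite to verify the seeded path on thousands
of instances; residual seeding misses are required to stay below 0.1% at
the tested divergences.

Tie-breaking is fixed everywhere so results are bit-reproducible: equal
scores resolve to the smaller contig start, then to the plus strand;
overlapping hits of one read are collapsed to the best-scoring hit per
locus.

## Coverage, repetitive classification, copy number

`depth[p]` counts alignments whose footprint covers position `p` — a
read aligning twice contributes twice. A position is repetitive when
`depth[p] ≥ 2` (exposed as `min_depth`): under a single-copy Poisson rate
of λ ≈ 0.036, P(depth ≥ 2) ≈ 6×10⁻⁴, so false classification is
negligible, while any locus with ≥ 50 genome-wide copies at the relevant
stringency is detected with high probability. The original analysis did
not state its rule; depth ≥ 2 is this package's choice and the flag makes
other rules available. Maps at several stringencies are derived from one
alignment pass at the laxest threshold by filtering on alignment
identity, which makes the stringency-monotonicity of the maps (depth at
0.99 pointwise ≤ depth at 0.75) structural rather than statistical.

Copy number divides mean interval depth by the genome-equivalent
coverage of the pool. Its precision is Poisson-limited by the number of
reads overlapping the interval, so short intervals at 0.036× carry large
relative errors; the package reports the raw ratio and leaves confidence
bounds to the caller.

## Element abundance

A read counts as matching an element when at least one alignment at or
above the identity cutoff covers ≥ 90% of the read. The read-count rule
(rather than aligned-base counting) reproduces the way element tables
count matching WGS reads; its known bias is inherited deliberately: a
60 bp read containing one 7 bp telomere motif is counted as a telomeric
read even though only 12% of its bases are telomeric, so motif portions
overstate motif base content. The motif assay also counts chance
background occurrences of the motif — at pine-like base composition the
7-mer TTTAGGG occurs spontaneously about once per 15 kb per strand — and
the test suite therefore scores it against an exact enumeration of
motif-containing genome windows, not against the planted array fraction
alone.

## Permissive consensus assembly

The assembler reconstructs the consensus of abundant repeat families
from a pool in which no two reads share a genomic locus. Design choices,
in the order they matter:

* **Seed**: the most frequent canonical 16-mer whose base-frequency
  entropy is ≥ 1.5 bits (the entropy filter rejects low-complexity
  words); ties break lexicographically.
* **Recruitment**: candidate read offsets are proposed by exact shared
  10-mers between read and the growing consensus, then verified
  ungapped: overlap ≥ 20 bp (capped by the current consensus extent
  while it is shorter) at ≥ 80% identity, both strands, best offset per
  read (most matches, then leftmost, then plus strand). The recruitment
  word is 10 rather than the seed's 16 because near the growing frontier
  the consensus is provisional and a read ~10% diverged from it must
  still share an exact word within a minimal overlap.
* **Extension**: columns are fixed by majority (ties: higher pool base
  frequency, then alphabetical). Extension proceeds provisionally
  wherever at least one recruited read reaches, because later recruits
  stack onto those columns retroactively; majority characters are
  refreshed every pass. After convergence, terminal columns that never
  reached `min_column_depth` (default 5) or lack a > 50% plurality base
  (overhang into unrelated flanks) are trimmed, so every interior column
  of a reported consensus carries at least the required depth.
* **Tandem guard**: recurrence of the seed word at a phase of ≤ 200 bp,
  or residual autocorrelation at a 5–200 bp period, stops extension and
  trims the consensus to one unit at the deepest phase, reporting
  `tandem_period`. Seed recurrence at longer phases is *not* treated as
  a tandem: an LTR element legitimately contains its seed twice, once
  per terminal repeat.
* **Iteration**: after each element, every read matching the consensus
  at the recruitment identity is subtracted, so the pool shrinks
  strictly; elements are ranked by supporting read count.

Two emergent behaviours are worth knowing. Reads wholly inside a
terminal repeat are ambiguous between the element's two LTR copies and
stack at the leftmost offset, so an LTR element assembles as the element
with *one* terminal repeat (sometimes cyclically rotated through it) —
its assembled length is the element length minus one LTR. And per-column
consensus accuracy follows the binomial majority bound: at per-read
divergence `d` and column depth `n` the error rate is at most
P(Bin(n, d) ≥ n/2), which the tests check against measured mismatch
counts.

## Repeat feature discovery on contigs

Direct-repeat (candidate LTR) pairs come from word-seeded (11-mer)
ungapped self-comparison with X-drop 20, excluding the main diagonal:
same-strand alignments ≥ 100 bp whose copies span ≥ 500 bp are reported,
with identity floor 0.50 chosen low enough to include weakly conserved
pairs; pairs touching an annotated exon are dropped when annotations are
supplied ("putatively noncoding"), and all sequence is eligible when they
are not. Hyper-repeated words (> 64 occurrences) are skipped during
seeding — such regions belong to the tandem detector.

The tandem detector is an original lag-correlation scan, not a
reimplementation of an existing tandem finder: for each period `p` in
5–200 bp, lag-`p` base matches are smoothed in windows of
`max(p, 12)` bp (the 12 bp floor suppresses chance matches at small
periods), runs at ≥ 80% match become arrays, and each array is reported
at the smallest period explaining it, with larger multiples suppressed
by overlap. The consensus unit is the column majority over unit-aligned
copies.

Simple repeats combine two rules: windows (64 bp, half-overlapping) with
base entropy < 1.0 bits, and exact mono-/di-/tri-/tetra-nucleotide units
repeated ≥ 8/6/5/5 times. ORF elements are ATG-to-stop frames ≥ 240 bp
on either strand; those overlapping supplied gene annotations are
dropped, only the longest ORF per overlapping cluster is reported, and a
coverage map can flag ORFs with ≥ 50% of their length in repetitive
positions. Running gene predictors is out of scope: "nongenic" is
defined strictly by the supplied annotation.

## Divergence profiling and its binning choice

Per replicate the profiler draws a fresh read pool at 0.036×
equivalents, samples non-overlapping 10 kb regions totalling 920 kb by
default, aligns the pool at ≥ 0.70 identity over ≥ 45 columns, and
assigns each region position to the identity bin (70–84 / 85–97 /
98–100%) of its best covering alignment; bins plus the unaligned
fraction sum to one per replicate, and replicates are averaged.
Covered-base accounting (rather than alignment counts, available
conceptually as the alternative) was chosen because it puts genomes of
different sizes on a common sampled-region denominator.

Two properties of best-alignment binning matter when reading profiles.
First, reads drawn from inside a sampled region align to their own locus
at ~100%, so the top bin always carries a floor roughly equal to the
pool coverage. Second, taking the maximum over the local alignment depth
shifts a family's positions slightly above its mean pairwise identity.
Both effects are visible in the tests' expectations: a family whose
copies are ~20% diverged from each other (per-copy substitution rate
0.12 from the consensus, expected pairwise identity
`(1-d)² + d²/3 ≈ 0.78`) concentrates in the 70–84 bin, while its top-bin
mass stays bounded by the coverage floor.

## The synthetic-genome generator

`simulate_genome()` plants repeat families into an i.i.d. background
drawn from a configurable base composition (default approximating the
measured A/C/G/T of large-conifer WGS reads, ~41% GC). Each family
consensus is drawn once; every copy is the consensus mutated
independently per base at the family divergence, so identity bookkeeping
in the ledger is exact. LTR families carry identical-at-birth terminal
repeats that diverge independently copy by copy; copies may be truncated
(random side, 30–90% kept) or nested — nesting splits the host into two
ledger fragments sharing one copy id, reproducing the interrupted
elements seen in real contigs. Tandem and telomeric families are planted
as arrays of mutated units; telomeric arrays use the exact 7-mer.
Indels are not simulated by default: the estimators are
substitution-framed, and substitution-only divergence keeps planted
identities exact. Reads are drawn uniformly in position and strand with
independent substitution errors; `N` bases never occur in simulated
reads.

`default_pine_spec()` bundles a desk-scale (10 Mb by default) landscape
emulating a large conifer genome: a young 4.2 kb LTR family at ~1.6% of
the genome (3% divergence), a 4 kb family at ~1.3% (5%), a 50 bp tandem
family at ~0.27%, telomeric arrays at ~0.24%, five ancient families at
20–30% divergence jointly holding ~55%, low-complexity tracts, and
compact multi-exon genes with five pseudogene copies per gene. Two
caveats about what this emulates. Copy *numbers* scale down with genome
size, so per-locus alignment depth at a fixed 0.036× coverage is far
below the real situation; validation scenarios therefore either raise
copy counts (coverage profiling) or raise pool coverage (assembly) to
restore realistic per-family read depth, and state so per test. And
"ancient at 20–30% per-copy divergence" implies pairwise copy identities
near 0.56–0.67 — *below* the 75% alignment threshold — so on desk-scale
genomes the lax-threshold repetitive fraction is carried by the younger
families; the qualitative 75%-versus-99% contrast is reproduced, the
real contigs' absolute percentages are not (they require the real data).

## Problem sizes and determinism

All validation runs are sized for a single CPU: genomes of 0.4–10 Mb,
pools of 10³–2×10⁵ reads, ten 100 kb null contigs for the
direct-repeat false-positive check, 1000 instances for the
aligner-versus-oracle equivalence, five replicates for divergence
profiles. One user-facing seed drives everything; module streams are
derived deterministically from it (`derive_seed`), and identical inputs
give bit-identical outputs, including through the command-line
interface.

## Known limitations

* Alignment sensitivity decays beyond ~15% read-to-contig divergence
  (word-8 seeding); families older than that are invisible to coverage
  profiling at any threshold it can support.
* The assembler's ambiguity handling collapses LTR pairs (one terminal
  repeat reported) and reports tandem families as a single unit; it does
  not reconstruct array lengths.
* Copy-number and abundance estimators assume uniform read sampling and
  substitution-style divergence; indel-rich families would be
  underestimated.
* The depth ≥ 2 repetitive rule and the 90% read-coverage matching rule
  are package choices where the original analysis is silent; both are
  exposed as parameters.
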