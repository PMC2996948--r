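# repeatscape

Repeat-landscape profiling of very large genomes from low-coverage
whole-genome shotgun (WGS) reads.

Conifer genomes (20–40 Gb) are dominated by repetitive elements that are
too diverged from one another to be catalogued by database similarity
alone. Long before such a genome can be assembled, a pool of short WGS
reads at far below 1× coverage already carries a genome-wide census of
its repeats: any sequence with many genomic copies is sampled many times
even when each locus is sampled less than once. `repeatscape` implements
the analyses that exploit this — identity-thresholded read coverage of
reference contigs, depth-ratio copy-number estimation, read-count
abundance estimation of repeat elements, permissive consensus assembly of
the most abundant repeat families, contig-level repeat feature discovery,
and identity-binned cross-genome divergence comparison — together with a
synthetic-genome simulator that plants repeats with a complete ground
truth ledger, so every estimator can be validated end to end.

## The estimators

With a genome of size `G`, a pool of `N` fixed-length reads of length `L`
has genome-equivalent coverage

    c = N · L / G        (e.g. 7.98e8 bases of a 22 Gb genome → 0.036×).

**Coverage profiling.** Reads are locally aligned to a reference contig
(match/mismatch +1/−1, linear gap cost 2 per column) at two stringencies,
by default ≥ 75% and ≥ 99% nucleotide identity. The per-base alignment
depth `d(p)` ("hits per base pair", exported as `.sgr`) classifies
position `p` as repetitive when `d(p) ≥ 2`: under single-copy coverage of
0.036× two independent reads essentially never stack, while a locus with
tens of genomic copies is almost surely covered twice.

**Copy number.** For an element spanning an interval `I` of the contig,

    copies = mean(d(p), p ∈ I) / c,

the ratio of its mean depth to the genome-equivalent coverage.

**Element abundance.** For an element consensus of length `ℓ` and a pool
of `N` reads of which `n` align to the consensus (≥ 75% identity over
≥ 90% of the read),

    genome portion = n / N,   total bp = (n/N) · G,   copies = total bp / ℓ,

with per-chromosome averages over the configured chromosome count. An
exact-motif assay applies the same bookkeeping to reads containing a short
motif such as the plant telomere repeat `TTTAGGG`.

**Permissive assembly.** At ≤ 0.04× no two reads truly overlap on the
genome, but reads from different copies of one family overlap on the
family consensus. Starting from the most frequent informative k-mer, the
assembler greedily recruits reads overlapping the growing consensus by
≥ 20 bp at ≥ 80% identity (both strands), stacks them at their best
offset, and sets each column to its most common base; extension stops
when column support falls below a depth threshold, and short-period seed
recurrence is folded into a tandem unit call.

**Divergence profiling.** Reads at 0.036× equivalents are aligned to
~920 kb of randomly sampled regions; every sampled position is assigned
to the identity bin (70–84 / 85–97 / 98–100%) of its best covering
alignment, replicated and averaged — a fingerprint of how diverged a
genome's repeats are that can be compared across genomes.

## Worked example

Published-scale bookkeeping from read-match counts (22 Gb genome, 12
chromosomes, pool of 21 million reads):

```r
library(repeatscape)
cfg <- analysis_config()
abundance_estimate("TPE1-like", 330219, 21e6, 4200, cfg)
#> Element TPE1-like
#>   matching reads:   330,219 of 2.1e+07
#>   genome portion:   1.57%
#>   total bp:         3.5e+08
#>   element length:   4200 bp
#>   copies in genome: 8.2e+04
```

A synthetic genome with planted families, profiled at both stringencies:

```r
fams <- list(
  repeat_family("agedLTR", 1200, copy_count = 400, divergence = 0.10),
  repeat_family("youngLTR", 800, copy_count = 150, divergence = 0))
truth <- simulate_genome(genome_spec(2e6, families = fams, seed = 1))
truth_fractions(truth)
#>     family     bp fraction copies
#> 1  agedLTR 480000     0.24    400
#> 2 youngLTR 120000     0.06    150

reads <- simulate_reads(truth, read_length_bp = 60, coverage = 0.036,
                        error_rate = 0.002, seed = 1)
contig <- substr(truth$sequences[[1]], 1, 30000)
maps <- coverage_maps(reads, contig, contig_id = "bac1",
                      thresholds = c(0.75, 0.99))
round(sapply(maps, repetitive_fraction), 3)
#> t0.75 t0.99
#> 0.240 0.098

copy_number(maps[["t0.75"]], 0, 30000)
#> Copy number of bac1:0-30000: mean depth 2.210 / coverage 0.036x = 61.4 copies
```

The 10%-diverged family is repetitive only at the lax threshold; the
identical family stays repetitive at 99% — the same contrast that
separates old from recently active repeat families in real coverage
tracks. `write_sgr()` serializes any map for genome-browser display, and
`run_cli()` (or `inst/cli/repeatscape`) chains the same steps from the
shell (`simulate`, `coverage`, `copynumber`, `abundance`, `telomere`,
`assemble`, `features`, `diverge`).

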