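# Shared fixtures, memoized so expensive simulations run once per session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

rand_dna <- function(n, seed = 1) {
  set.seed(seed)
  repeatscape:::random_dna(n)
}

mutate_dna <- function(s, rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeatscape:::mutate_seq_cpp(s, rate)$seq
}

rc <- function(s) repeatscape:::revcomp(s)

# genome with one family occupying ~30% at 10% per-copy divergence plus a
# young identical family; used by coverage tests and the stringency
# acceptance check
fx_coverage_case <- function() fixture("coverage_case", {
  fams <- list(
    repeat_family("aged", 1200L, copy_count = 400L, divergence = 0.10),
    repeat_family("young", 800L, copy_count = 150L, divergence = 0))
  truth <- simulate_genome(genome_spec(2e6, families = fams, seed = 31))
  reads <- simulate_reads(truth, 60, coverage = 0.036, error_rate = 0.002,
                          seed = 32)
  list(truth = truth, reads = reads)
})

# desk-scale pine-like genome (4 Mb) for the bundled-spec tests
fx_pine <- function() fixture("pine", {
  simulate_genome(default_pine_spec(seed = 7, genome_length_bp = 4e6))
})

# per-replicate divergence-profile genomes with equal repeat totals
fx_div_genome <- function(divergence, seed) {
  fam <- repeat_family("rep", 3000L, copy_count = 80L,
                       divergence = divergence)
  simulate_genome(genome_spec(8e5, families = list(fam), seed = seed))
}

# fraction of true-consensus columns recovered by `sequence` at or above
# `min_identity`, plus the mismatch count over the aligned pieces
consensus_recovery <- function(sequence, true_consensus,
                               min_identity = 0.99) {
  o <- sw_oracle(sequence, true_consensus, min_identity = min_identity,
                 min_aln_len = 100L, max_contig_bp = 30000L)
  if (!nrow(o)) return(list(coverage = 0, n_mismatch = NA))
  iv <- cbind(o$read_start, o$read_end)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  cov <- 0
  last <- 0
  for (i in seq_len(nrow(iv))) {
    a <- max(iv[i, 1], last)
    if (iv[i, 2] > a) { cov <- cov + (iv[i, 2] - a); last <- iv[i, 2] }
  }
  list(coverage = cov / nchar(sequence), n_mismatch = sum(o$n_mismatch))
}
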