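test_that("simulation is deterministic given spec and seed", {
  fam <- repeat_family("f", 500L, copy_count = 20L, divergence = 0.05)
  spec <- genome_spec(1e5, families = list(fam), seed = 99)
  t1 <- simulate_genome(spec)
  t2 <- simulate_genome(spec)
  expect_identical(t1$sequences, t2$sequences)
  expect_identical(t1$placements, t2$placements)
  r1 <- simulate_reads(t1, 40, coverage = 0.05, error_rate = 0.01, seed = 4)
  r2 <- simulate_reads(t2, 40, coverage = 0.05, error_rate = 0.01, seed = 4)
  expect_identical(r1$reads, r2$reads)
})

test_that("planted fractions follow copy count x length exactly at zero divergence", {
  fam <- repeat_family("f", 400L, copy_count = 100L, divergence = 0)
  truth <- simulate_genome(genome_spec(1e6, families = list(fam), seed = 5))
  tf <- truth_fractions(truth)
  expect_equal(tf$fraction, 100 * 400 / 1e6)
  expect_equal(tf$copies, 100L)
  expect_true(all(truth$placements$identity == 1))
})

test_that("per-copy divergence is recovered within 3 SE of the spec rate", {
  d <- 0.05; len <- 500L; n <- 200L
  fam <- repeat_family("f", len, copy_count = n, divergence = d)
  truth <- simulate_genome(genome_spec(5e5, families = list(fam), seed = 6))
  # oracle: count mismatches of each placement against the stored consensus
  cons <- truth$consensi[["f"]]
  pl <- truth$placements
  g <- truth$sequences[[1]]
  seqs <- substring(g, pl$start + 1L, pl$end)
  seqs[pl$strand == "-"] <- rc(seqs[pl$strand == "-"])
  mm <- repeatscape:::count_mismatches_cpp(seqs, rep(cons, nrow(pl)))
  obs <- 1 - sum(mm) / (as.numeric(len) * n)
  se <- sqrt(d * (1 - d) / (as.numeric(len) * n))
  expect_lt(abs(obs - (1 - d)), 3 * se)
  # the ledger identities equal the directly measured ones
  expect_equal(pl$identity, 1 - mm / len)
})

test_that("placements stay in bounds and do not overlap", {
  truth <- fx_pine()
  pl <- truth$placements
  G <- nchar(truth$sequences[[1]])
  expect_true(all(pl$start >= 0 & pl$end <= G & pl$start < pl$end))
  expect_true(all(diff(pl$start) >= 0))
  expect_true(all(utils::head(pl$end, -1) <= utils::tail(pl$start, -1)))
})

test_that("read pools have the configured size, sources and error rate", {
  fam <- repeat_family("f", 400L, copy_count = 50L, divergence = 0.02)
  truth <- simulate_genome(genome_spec(1e6, families = list(fam), seed = 8))
  rs <- simulate_reads(truth, 60, coverage = 0.036, seed = 9)
  expect_equal(rs$n, round(0.036 * 1e6 / 60))
  expect_equal(rs$total_bases, rs$n * 60)

  # error-free reads are exact substrings of the genome or its complement
  g <- truth$sequences[[1]]
  src <- rs$sources
  orig <- substring(g, src$start + 1L, src$start + 60L)
  orig[src$strand == "-"] <- rc(orig[src$strand == "-"])
  expect_identical(rs$reads, unname(orig))

  # substitution errors land at the configured rate (3 SE)
  rs2 <- simulate_reads(truth, 60, coverage = 0.6, error_rate = 0.01,
                        seed = 10)
  src2 <- rs2$sources
  orig2 <- substring(g, src2$start + 1L, src2$start + 60L)
  orig2[src2$strand == "-"] <- rc(orig2[src2$strand == "-"])
  mm <- sum(repeatscape:::count_mismatches_cpp(rs2$reads, orig2))
  nbase <- rs2$n * 60
  expect_lt(abs(mm - 0.01 * nbase), 3 * sqrt(nbase * 0.01 * 0.99))
  expect_equal(mm, sum(src2$n_errors))
})

test_that("read starts are uniform over the genome", {
  g <- rand_dna(5e5, 11)
  rs <- simulate_reads(g, 40, coverage = 8, seed = 12)  # 1e5 reads
  expect_equal(rs$n, 1e5)
  bins <- cut(rs$sources$start, breaks = 20)
  p <- suppressWarnings(stats::chisq.test(table(bins))$p.value)
  expect_gt(p, 0.001)
})

test_that("the bundled pine-like spec plants the advertised landscape", {
  truth <- fx_pine()
  tf <- truth_fractions(truth)
  young <- tf$fraction[tf$family == "youngLTR"]
  expect_lt(abs(young - 0.016) / 0.016, 0.10)
  expect_lt(abs(tf$fraction[tf$family == "tel_rpt"] - 0.0024) / 0.0024, 0.15)
  # ancient families jointly dominate
  anc <- sum(tf$fraction[grepl("^ancient", tf$family)])
  expect_gt(anc, 0.4)

  # five pseudogenes per gene, as configured
  pl <- truth$placements
  n_gene <- length(unique(pl$copy_id[pl$family == "gene"]))
  n_pseudo <- length(unique(pl$copy_id[pl$family == "pseudogene"]))
  expect_equal(n_pseudo, 5L * n_gene)

  # determinism of the bundled spec
  t2 <- simulate_genome(default_pine_spec(seed = 7, genome_length_bp = 4e6))
  expect_identical(truth$sequences, t2$sequences)
})

test_that("oversized placements are rejected", {
  fam <- repeat_family("f", 1000L, copy_count = 200L)
  expect_error(simulate_genome(genome_spec(1e5, families = list(fam))),
               "exceed")
})
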