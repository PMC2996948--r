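test_that("assembly parameters are validated", {
  expect_error(assembly_params(min_overlap_identity = 0.4), "0.5")
  expect_error(assembly_params(k = 4), "at least 8")
  p <- assembly_params()
  expect_equal(p$k, 16L)
  expect_equal(p$min_column_depth, 5L)
})

test_that("seed selection picks a frequent informative word", {
  el <- rand_dna(200, 51)
  offs <- seq(1, 161, by = 5)
  reads <- read_set(rep(substring(el, offs, offs + 39), 10))
  sd <- select_seed(reads)
  expect_true(grepl(sd, el, fixed = TRUE) || grepl(rc(sd), el, fixed = TRUE))

  polya <- read_set(rep(strrep("A", 40), 100))
  expect_error(select_seed(polya), "low-complexity")
})

test_that("the seed comes from the more abundant family nearly always", {
  set.seed(52)
  wins <- 0
  for (i in 1:100) {
    a <- repeatscape:::random_dna(300, rep(0.25, 4))
    b <- repeatscape:::random_dna(300, rep(0.25, 4))
    s <- sample(1:261, 180, TRUE)
    pool <- substring(c(a, b)[c(rep(1, 120), rep(2, 60))], s, s + 39)
    sd <- select_seed(read_set(pool))
    if (grepl(sd, a, fixed = TRUE) || grepl(rc(sd), a, fixed = TRUE))
      wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("tiling reads over identical copies reproduce the element exactly", {
  el <- rand_dna(200, 53)
  offs <- seq(1, 161, by = 5)
  reads <- read_set(rep(substring(el, offs, offs + 39), 100))
  cons <- extend_consensus(reads, substr(el, 81, 96))
  expect_equal(cons$sequence, el)
  expect_equal(cons$supporting_read_count, reads$n)
  # every interior column carries at least the required depth
  expect_true(all(utils::head(utils::tail(cons$depth, -2), -2) >= 5))
})

test_that("a diverged family is recovered near-perfectly at high identity", {
  fam <- repeat_family("fam", 1000L, copy_count = 500L, divergence = 0.05)
  truth <- simulate_genome(genome_spec(8e5, families = list(fam), seed = 3))
  reads <- simulate_reads(truth, 40, coverage = 0.04, error_rate = 0.005,
                          seed = 5)
  el <- extend_consensus(reads, select_seed(reads))
  rec <- consensus_recovery(el$sequence, truth$consensi[["fam"]], 0.99)
  expect_gte(rec$coverage, 0.95)
  # majority-rule error bound: observed consensus errors cannot exceed
  # three times the binomial column-flip expectation (plus a 3-column floor)
  d <- 0.055  # per-read divergence from the family consensus incl. errors
  exp_err <- sum(stats::pbinom(ceiling(el$depth / 2) - 1, el$depth, d,
                               lower.tail = FALSE))
  expect_lte(rec$n_mismatch, 3 * exp_err + 3)
})

test_that("tandem arrays terminate with the unit period detected", {
  fam <- repeat_family("cen", 50L, copy_count = 2000L, divergence = 0.02,
                       kind = "tandem")
  truth <- simulate_genome(genome_spec(6e5, families = list(fam), seed = 8))
  reads <- simulate_reads(truth, 40, coverage = 0.05, seed = 2)
  el <- extend_consensus(reads, select_seed(reads))
  expect_equal(el$structure$tandem_period, 50L)
  expect_equal(nchar(el$sequence), 50L)
  u <- truth$consensi[["cen"]]
  expect_true(grepl(el$sequence, strrep(u, 2), fixed = TRUE) ||
                grepl(el$sequence, rc(strrep(u, 2)), fixed = TRUE))

  tel <- repeat_family("tel", 7L, copy_count = 6000L, kind = "telomeric")
  truth2 <- simulate_genome(genome_spec(6e5, families = list(tel), seed = 8))
  reads2 <- simulate_reads(truth2, 40, coverage = 0.05, seed = 2)
  el2 <- extend_consensus(reads2, select_seed(reads2))
  expect_equal(el2$structure$tandem_period, 7L)
  expect_true(grepl(el2$sequence, strrep("TTTAGGG", 3), fixed = TRUE) ||
                grepl(el2$sequence, rc(strrep("TTTAGGG", 3)), fixed = TRUE))
})

test_that("assembly is deterministic for a fixed pool", {
  fam <- repeat_family("f", 600L, copy_count = 300L, divergence = 0.03)
  truth <- simulate_genome(genome_spec(4e5, families = list(fam), seed = 55))
  reads <- simulate_reads(truth, 40, coverage = 0.05, seed = 56)
  e1 <- extend_consensus(reads, select_seed(reads))
  e2 <- extend_consensus(reads, select_seed(reads))
  expect_identical(e1$sequence, e2$sequence)
  expect_identical(e1$depth, e2$depth)
  expect_error(extend_consensus(reads, strrep("ACGT", 4)), "does not occur")
})

test_that("iterated assembly ranks families by read support", {
  fams <- list(repeat_family("big", 800L, copy_count = 240L,
                             divergence = 0.02),
               repeat_family("small", 700L, copy_count = 100L,
                             divergence = 0.02))
  truth <- simulate_genome(genome_spec(5e5, families = fams, seed = 57))
  reads <- simulate_reads(truth, 40, coverage = 0.06, seed = 58)
  els <- assemble_top_repeats(reads, assembly_params(max_elements = 2L))
  expect_equal(length(els), 2L)
  expect_gt(els[[1]]$supporting_read_count, els[[2]]$supporting_read_count)
  r1 <- consensus_recovery(els[[1]]$sequence, truth$consensi[["big"]], 0.95)
  r2 <- consensus_recovery(els[[2]]$sequence, truth$consensi[["small"]], 0.95)
  expect_gte(r1$coverage, 0.9)
  expect_gte(r2$coverage, 0.9)
})

test_that("a pure background pool yields no elements", {
  set.seed(59)
  g <- rand_dna(1e6, 60)
  reads <- simulate_reads(g, 40, coverage = 0.03, seed = 61)
  els <- assemble_top_repeats(reads, assembly_params(max_elements = 2L))
  expect_equal(length(els), 0L)
})

test_that("structure detection finds terminal pairs and periodicity", {
  ltr <- rand_dna(300, 62)
  el <- paste0(ltr, rand_dna(1000, 63), ltr)
  st <- detect_structure(el)
  expect_false(is.null(st$ltr_pair))
  expect_equal(st$ltr_pair$identity, 1.0)
  expect_equal(st$ltr_pair$start1, 0L)
  expect_equal(st$ltr_pair$end2, nchar(el))

  expect_equal(detect_structure(strrep("ACGTG", 30))$tandem_period, 5L)

  # diverged terminal repeats: reported identity tracks the planted pair
  l1 <- mutate_dna(ltr, 0.05, seed = 64)
  l2 <- mutate_dna(ltr, 0.05, seed = 65)
  pair_id <- 1 - sum(repeatscape:::count_mismatches_cpp(l1, l2)) / 300
  st2 <- detect_structure(paste0(l1, rand_dna(1000, 66), l2))
  expect_false(is.null(st2$ltr_pair))
  expect_lt(abs(st2$ltr_pair$identity - pair_id), 0.03)

  expect_error(detect_structure("ACGT"), "at least 50")
})
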