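test_that("genome-equivalent coverage reproduces the published pool sizes", {
  expect_equal(round(genome_equivalents(7.98e8, 2.2e10), 3), 0.036)
  expect_equal(round(genome_equivalents(5.38e8, 2.2e10), 3), 0.024)
  expect_equal(round(genome_equivalents(3.28e8, 2.2e10), 3), 0.015)
  expect_equal(genome_equivalents(5, 5), 1.0)
  expect_error(genome_equivalents(1, 0), "positive")
})

test_that("abundance bookkeeping reproduces the worked element table", {
  cfg <- analysis_config()  # 2.2e10 bp, 12 chromosomes
  tpe1 <- abundance_estimate("TPE1", 330219, 21e6, 4200, cfg)
  expect_equal(signif(100 * tpe1$genome_portion, 3), 1.57)
  expect_equal(signif(tpe1$copies, 2), 82000)
  expect_equal(signif(tpe1$total_bp, 2), 3.5e8)

  ifg7 <- abundance_estimate("PtIFG7", 281712, 21e6, 4000, cfg)
  expect_equal(signif(100 * ifg7$genome_portion, 3), 1.34)
  expect_equal(signif(ifg7$copies, 2), 74000)
  expect_equal(signif(ifg7$total_bp, 2), 3.0e8)

  cen <- abundance_estimate("cen-rpt", 57524, 21e6, 50, cfg)
  expect_equal(signif(100 * cen$genome_portion, 2), 0.27)
  expect_equal(signif(cen$total_bp, 2), 6.0e7)

  tel <- abundance_estimate("tel-rpt", 50494, 21e6, 7, cfg)
  expect_equal(signif(100 * tel$genome_portion, 2), 0.24)
  expect_equal(signif(tel$total_bp, 2), 5.3e7)

  # internal consistency: all derived fields recompute from the inputs
  expect_equal(tpe1$copies * tpe1$element_length_bp, tpe1$total_bp)
  expect_equal(tpe1$per_chromosome_copies * cfg$n_chromosomes, tpe1$copies)
  expect_equal(tpe1$per_chromosome_bp * cfg$n_chromosomes, tpe1$total_bp)
  expect_error(abundance_estimate("x", 10, 0, 100), "empty")
  expect_error(abundance_estimate("x", 11, 10, 100), "between")
})

test_that("genome percentages follow the configured genome size", {
  expect_equal(signif(genome_fraction(923817), 2), 0.0042)
  expect_equal(genome_fraction(0), 0)
  expect_equal(genome_fraction(2.2e10), 100)
})

test_that("base composition sums to one and reports GC", {
  expect_equal(unname(gc_content("GGCC")["GC"]), 1.0)
  expect_equal(unname(gc_content("ATAT")["GC"]), 0.0)
  fr <- gc_content(rand_dna(5000, 40))
  expect_equal(sum(fr[c("A", "C", "G", "T")]), 1, tolerance = 1e-12)
  expect_error(gc_content(character(0)), "empty")
})

test_that("element quantification recovers a planted genome portion", {
  fam <- repeat_family("tpe1", 4200L, copy_count = 10L, divergence = 0.005)
  truth <- simulate_genome(genome_spec(2.1e6, families = list(fam), seed = 41))
  reads <- simulate_reads(truth, 42, coverage = 2.0, error_rate = 0.002,
                          seed = 42)
  cfg <- analysis_config(genome_size_bp = 2.1e6)
  est <- quantify_element(reads, truth$consensi[["tpe1"]], config = cfg)
  # binomial oracle: reads with >= 90% of their bases inside a placement
  pl <- truth$placements
  p0 <- sum(pl$end - pl$start - 33) / (2.1e6 - 42 + 1)
  se <- sqrt(p0 * (1 - p0) / reads$n)
  expect_lt(abs(est$genome_portion - p0), 3 * se + 0.001)
  expect_lt(abs(est$genome_portion - 0.02), 0.002)
})

test_that("estimates degrade monotonically once divergence exceeds the cutoff", {
  ests <- sapply(c(0.05, 0.20), function(d) {
    fam <- repeat_family("f", 2000L, copy_count = 10L, divergence = d)
    truth <- simulate_genome(genome_spec(1e6, families = list(fam),
                                         seed = 43))
    reads <- simulate_reads(truth, 40, coverage = 1.0, seed = 44)
    quantify_element(reads, truth$consensi[["f"]], min_identity = 0.75,
                     config = analysis_config(genome_size_bp = 1e6)
                     )$genome_portion
  })
  expect_gt(ests[1], ests[2])  # 20% divergence falls below the 75% cutoff
  expect_lt(abs(ests[1] - 0.02), 0.005)
})

test_that("the motif assay counts reads containing the telomere repeat", {
  fam <- repeat_family("tel", 7L, copy_count = round(0.005 * 1e6 / 7),
                       kind = "telomeric")
  truth <- simulate_genome(genome_spec(1e6, families = list(fam), seed = 45))
  reads <- simulate_reads(truth, 60, coverage = 1.2, seed = 46)
  cfg <- analysis_config(genome_size_bp = 1e6)
  est <- motif_assay(reads, "TTTAGGG", cfg)
  # exact enumeration oracle: fraction of 60-mer windows containing the motif
  g <- truth$sequences[[1]]
  starts <- sort(unique(c(gregexpr("TTTAGGG", g, fixed = TRUE)[[1]],
                          gregexpr(rc("TTTAGGG"), g, fixed = TRUE)[[1]])))
  starts <- starts[starts > 0]
  win <- logical(nchar(g) - 59)
  for (s in starts) {
    a <- max(1, s - 53)
    b <- min(length(win), s)
    if (b >= a) win[a:b] <- TRUE
  }
  p0 <- mean(win)
  se <- sqrt(p0 * (1 - p0) / reads$n)
  expect_lt(abs(est$genome_portion - p0), 3 * se)

  none <- read_set(replicate(50, rand_dna(60, sample.int(1e6, 1))))
  expect_equal(motif_assay(none, "TTTAGGGTTTAGGGTTTAGGG",
                           cfg)$genome_portion, 0)
  expect_error(motif_assay(none, ""), "empty motif")
})

test_that("combined portions of disjoint families stay below one", {
  fams <- list(repeat_family("a", 1000L, copy_count = 30L, divergence = 0.01),
               repeat_family("b", 800L, copy_count = 30L, divergence = 0.01))
  truth <- simulate_genome(genome_spec(5e5, families = fams, seed = 47))
  reads <- simulate_reads(truth, 40, coverage = 1.0, seed = 48)
  cfg <- analysis_config(genome_size_bp = 5e5)
  pa <- quantify_element(reads, truth$consensi[["a"]], config = cfg)
  pb <- quantify_element(reads, truth$consensi[["b"]], config = cfg)
  expect_lt(pa$genome_portion + pb$genome_portion, 1)
  rep <- abundance_report(list(pa, pb))
  expect_equal(nrow(rep), 2L)
  expect_true(all(c("genome_portion_pct", "copies") %in% names(rep)))
})
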