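# background built only from T/A/C with stop codons in every reading frame
# of the plus strand and no ATG on either strand (for ORF tests)
orf_free_bg <- function(n) substr(strrep("TAAC", ceiling(n / 4)), 1, n)

test_that("planted direct-repeat pairs are found with exact geometry", {
  rep150 <- rand_dna(150, 71)
  contig <- paste0(rand_dna(500, 72), rep150, rand_dna(1000, 73), rep150,
                   rand_dna(500, 74))
  dr <- find_direct_repeats(contig)
  expect_equal(nrow(dr), 1L)
  # boundaries may shift by a few chance-matching flank bases
  expect_lt(abs(dr$start1 - 500L), 6)
  expect_lt(abs(dr$start2 - 1650L), 6)
  expect_lt(abs(dr$span_bp - 1300L), 12)
  expect_gte(dr$identity, 0.97)
  expect_gte(dr$length, 150L)
})

test_that("pair identity tracks the planted divergence", {
  base <- rand_dna(200, 75)
  r1 <- mutate_dna(base, 0.05, seed = 76)
  r2 <- mutate_dna(base, 0.05, seed = 77)
  true_id <- 1 - sum(repeatscape:::count_mismatches_cpp(r1, r2)) / 200
  contig <- paste0(rand_dna(400, 78), r1, rand_dna(800, 79), r2,
                   rand_dna(400, 80))
  dr <- find_direct_repeats(contig)
  expect_equal(nrow(dr), 1L)
  expect_lt(abs(dr$identity - true_id), 0.03)
})

test_that("short pairs and short spans are excluded by the reporting rules", {
  rep80 <- rand_dna(80, 81)
  contig <- paste0(rand_dna(500, 82), rep80, rand_dna(1000, 83), rep80,
                   rand_dna(500, 84))
  expect_equal(nrow(find_direct_repeats(contig)), 0L)  # min_len 100

  rep120 <- rand_dna(120, 85)
  near <- paste0(rand_dna(500, 86), rep120, rand_dna(100, 87), rep120,
                 rand_dna(500, 88))
  expect_equal(nrow(find_direct_repeats(near)), 0L)   # span < 500
  expect_equal(nrow(find_direct_repeats(near, min_span = 300L)), 1L)
})

test_that("pairs overlapping annotated exons are dropped as genic", {
  rep150 <- rand_dna(150, 89)
  contig <- paste0(rand_dna(500, 90), rep150, rand_dna(1000, 91), rep150,
                   rand_dna(500, 92))
  ann <- data.frame(contig_id = "contig", type = "exon",
                    start = 520L, end = 600L, stringsAsFactors = FALSE)
  expect_equal(nrow(find_direct_repeats(contig, annotations = ann)), 0L)
  ann2 <- data.frame(contig_id = "contig", type = "exon",
                     start = 3000L, end = 3100L, stringsAsFactors = FALSE)
  expect_equal(nrow(find_direct_repeats(contig, annotations = ann2)), 1L)
})

test_that("no direct-repeat pairs arise from repeat-free random contigs", {
  for (seed in 1:10) {
    contig <- rand_dna(1e5, 700 + seed)
    expect_equal(nrow(find_direct_repeats(contig)), 0L)
  }
})

test_that("planted candidate-LTR pairs are recalled from a synthetic genome", {
  fam <- repeat_family("ltr", 2000L, copy_count = 15L, divergence = 0.08,
                       ltr_length_bp = 300L)
  truth <- simulate_genome(genome_spec(3e5, families = list(fam), seed = 93))
  contig <- truth$sequences[[1]]
  dr <- find_direct_repeats(contig)
  pl <- truth$placements
  intact <- pl[!pl$truncated, , drop = FALSE]
  found <- vapply(seq_len(nrow(intact)), function(i) {
    s <- intact$start[i]; e <- intact$end[i]
    any(dr$start1 >= s - 50 & dr$start1 < s + 350 &
          dr$end2 > e - 350 & dr$end2 <= e + 50)
  }, TRUE)
  expect_gte(mean(found), 0.9)
})

test_that("tandem arrays are detected at their minimal period", {
  arr <- strrep("ACGTG", 30)
  contig <- paste0(rand_dna(400, 94), arr, rand_dna(400, 95))
  tr <- find_tandem_repeats(contig)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$period_bp, 5L)
  expect_equal(tr$copy_number, 30, tolerance = 0.05)
  expect_equal(tr$consensus_unit,
               substr(strrep("ACGTG", 2), (tr$start %% 5) + 1,
                      (tr$start %% 5) + 5))

  # a unit above the size bound is not reported
  unit201 <- rand_dna(201, 96)
  big <- paste0(rand_dna(300, 97), strrep(unit201, 3), rand_dna(300, 98))
  expect_equal(nrow(find_tandem_repeats(big)), 0L)
})

test_that("a diverged 50 bp array is recovered with its expected match level", {
  unit <- rand_dna(50, 99)
  d <- 0.05
  set.seed(100)
  copies <- vapply(1:40, function(i) mutate_dna(unit, d), "")
  contig <- paste0(rand_dna(500, 101), paste(copies, collapse = ""),
                   rand_dna(500, 102))
  tr <- find_tandem_repeats(contig)
  expect_gte(nrow(tr), 1L)
  main <- tr[which.max(tr$end - tr$start), ]
  expect_equal(main$period_bp, 50L)
  # lag-50 match rate between independent mutated copies
  exp_match <- (1 - d)^2 + d^2 / 3
  se <- sqrt(exp_match * (1 - exp_match) / (main$end - main$start - 50))
  expect_lt(abs(main$percent_match - exp_match), 4 * se)
  expect_gte(main$copy_number, 2)
})

test_that("simple repeats are called by entropy and unit rules only where planted", {
  contig <- paste0(rand_dna(300, 103), strrep("A", 100), rand_dna(300, 104))
  sr <- find_simple_repeats(contig)
  expect_gte(nrow(sr), 1L)
  hit <- sr[which.max(sr$end - sr$start), ]
  expect_lte(hit$start, 310L)
  expect_gte(hit$end, 390L)

  micro <- paste0(rand_dna(300, 105), strrep("AT", 50), rand_dna(300, 106))
  sm <- find_simple_repeats(micro)
  expect_gte(nrow(sm), 1L)
  expect_true(any(sm$label %in% c("di", "low_entropy")))

  # random uniform sequence: no low-entropy windows; at most one chance
  # short-unit run
  rand <- rand_dna(10000, 107)
  sr0 <- find_simple_repeats(rand)
  expect_equal(sum(sr0$label == "low_entropy"), 0L)
  expect_lte(nrow(sr0), 1L)
})

test_that("long nongenic ORFs are reported under the published rules", {
  mk_orf <- function(n_codons, seed) {
    set.seed(seed)
    codons <- c("GCT", "GGA", "TGC", "CTG", "GAC", "TTC", "AAC", "CGA")
    paste0("ATG", paste(sample(codons, n_codons - 2, TRUE), collapse = ""),
           "TAA")
  }
  orf300 <- mk_orf(100, 108)   # 300 bp
  orf150 <- mk_orf(50, 109)    # 150 bp
  contig <- paste0(orf_free_bg(600), orf300, orf_free_bg(600), orf150,
                   orf_free_bg(600))
  found <- find_orf_elements(contig)
  # one cluster is reported, anchored on the planted 300 bp ORF (an
  # overlapping out-of-frame ORF may win the cluster by a few bases)
  expect_equal(nrow(found), 1L)
  ov <- min(found$end, 900L) - max(found$start, 600L)
  expect_gte(ov / 300, 0.8)
  expect_gte(found$length, 240L)
  expect_equal(found$length %% 3, 0L)
  # the 150 bp ORF region yields nothing
  expect_false(any(found$start > 1400L))

  # the same ORF inside an annotated gene is excluded
  ann <- data.frame(contig_id = "contig", type = "gene",
                    start = 550L, end = 950L, stringsAsFactors = FALSE)
  expect_equal(nrow(find_orf_elements(contig, gene_annotations = ann)), 0L)

  # repetitive-coverage flag from a coverage map
  depth <- rep(0L, nchar(contig))
  depth[601:900] <- 3L
  cm <- repeatscape:::coverage_map_from_depth(depth)
  flagged <- find_orf_elements(contig, covmap = cm)
  expect_true(flagged$overlaps_repetitive_coverage[1])
})

test_that("feature summaries count each class per contig", {
  rep150 <- rand_dna(150, 110)
  contig <- paste0(rand_dna(400, 111), rep150, rand_dna(900, 112), rep150,
                   strrep("ACGTG", 30), rand_dna(400, 113))
  s <- repeat_feature_summary(contig, contig_id = "c1")
  expect_equal(s$contig_id, "c1")
  expect_gte(s$direct_repeat_pairs, 1L)
  expect_gte(s$tandem_repeats, 1L)
})
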