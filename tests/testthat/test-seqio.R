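test_that("read_fasta normalizes case and RNA bases", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">x demo record", "acgu"), f)
  rec <- read_fasta(f)
  expect_equal(rec$id, "x")
  expect_equal(rec$sequence, "ACGT")
  expect_equal(rec$description, "demo record")
})

test_that("read_fasta rejects malformed files with named failures", {
  dup <- tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGT", ">x", "GGTT"), dup)
  expect_error(read_fasta(dup), "duplicate sequence id")

  bad <- tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGQ"), bad)
  expect_error(read_fasta(bad), "illegal character")

  emp <- tempfile(fileext = ".fa")
  writeLines(c(">x", ">y", "ACGT"), emp)
  expect_error(read_fasta(emp), "empty sequence")

  expect_error(read_fasta(tempfile()), "not found")
})

test_that("write_fasta wraps lines and round-trips byte-identically", {
  set.seed(5)
  seq130 <- rand_dna(130, 5)
  f <- tempfile(fileext = ".fa")
  write_fasta(c(el = seq130), f, wrap = 60)
  lines <- readLines(f)
  expect_equal(length(lines), 4L)  # header + 60/60/10
  expect_equal(nchar(lines[2:4]), c(60L, 60L, 10L))

  rec <- read_fasta(f)
  expect_equal(rec$sequence, seq130)
  f2 <- tempfile(fileext = ".fa")
  write_fasta(rec, f2, wrap = 60)
  expect_identical(readLines(f), readLines(f2))

  expect_error(write_fasta(data.frame(), f), "no records")
})

test_that("read_reads enforces a single read length and counts bases", {
  f <- tempfile(fileext = ".fa")
  set.seed(2)
  write_fasta(stats::setNames(replicate(10, rand_dna(60, sample.int(1e6, 1))),
                              sprintf("r%02d", 1:10)), f)
  rs <- read_reads(f)
  expect_s3_class(rs, "read_set")
  expect_equal(rs$n, 10L)
  expect_equal(rs$read_length, 60L)
  expect_equal(rs$total_bases, 600)

  mix <- tempfile(fileext = ".fa")
  writeLines(c(">a", strrep("A", 40), ">b", strrep("C", 60)), mix)
  expect_error(read_reads(mix), "mixed read lengths.*b")
})

test_that("FASTQ reads parse with qualities ignored downstream", {
  f <- tempfile(fileext = ".fq")
  set.seed(3)
  sq <- replicate(4, rand_dna(60, sample.int(1e6, 1)))
  writeLines(as.vector(rbind(paste0("@r", 1:4), sq, "+", strrep("I", 60))), f)
  rs <- read_reads(f, format = "fastq")
  expect_equal(rs$n, 4L)
  expect_equal(rs$read_length, 60L)
  expect_equal(rs$reads, unname(sq))

  bad <- tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+"), bad)  # missing quality line
  expect_error(read_reads(bad, format = "fastq"), "malformed FASTQ")
})

test_that(".sgr output is 1-based, dense and round-trips", {
  cm <- repeatscape:::coverage_map_from_depth(c(0L, 2L, 1L), "b1")
  f <- tempfile(fileext = ".sgr")
  write_sgr(cm, f)
  expect_identical(readLines(f), c("b1\t1\t0", "b1\t2\t2", "b1\t3\t1"))

  back <- read_sgr(f)
  expect_identical(back$depth, cm$depth)
  expect_identical(back$contig_id, "b1")

  empty <- repeatscape:::coverage_map_from_depth(integer(0), "b1")
  expect_error(write_sgr(empty, f), "empty coverage map")

  gap <- tempfile(fileext = ".sgr")
  writeLines(c("b1\t1\t0", "b1\t3\t2"), gap)
  expect_error(read_sgr(gap), "dense")
})

test_that("GFF3 I/O converts between 1-based inclusive and 0-based half-open", {
  iv <- data.frame(contig_id = "c1", start = 0L, end = 5L, strand = "+",
                   type = "repeat_copy", family = "fam1",
                   identity = 0.95, stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".gff3")
  write_gff3(iv, f)
  raw <- readLines(f)
  row <- strsplit(grep("repeat_copy", raw, value = TRUE)[1], "\t")[[1]]
  expect_equal(as.integer(row[4:5]), c(1L, 5L))

  back <- read_gff3(f)
  expect_equal(back$start, 0L)
  expect_equal(back$end, 5L)
  expect_equal(back$strand, "+")
  expect_equal(back$type, "repeat_copy")
  expect_equal(back$family, "fam1")
  expect_equal(as.numeric(back$identity), 0.95)

  f2 <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tsrc\tgene\t11\t20\t.\t-\t.\tID=g1;Name=demo"), f2)
  g <- read_gff3(f2)
  expect_equal(g$start, 10L)
  expect_equal(g$end, 20L)
  expect_equal(g$source, "src")
  expect_equal(g$ID, "g1")
  expect_equal(g$Name, "demo")

  expect_error(write_gff3(data.frame(contig_id = "c", start = 5L, end = 5L),
                          f), "invalid interval")
})

test_that("BED6 export writes six columns with 0-based starts", {
  iv <- data.frame(contig_id = "c1", start = 3L, end = 9L,
                   name = "seg", strand = "-", stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".bed")
  write_bed(iv, f)
  row <- strsplit(readLines(f), "\t")[[1]]
  expect_equal(row, c("c1", "3", "9", "seg", "0", "-"))
})
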