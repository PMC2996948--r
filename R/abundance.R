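# Read-count abundance estimators for repeat elements, exact-motif
# (telomere) assays, and composition statistics.

#' Genome-equivalent coverage of a read pool
#'
#' @param total_read_bases Total bases in the pool.
#' @param genome_size Genome size in bp.
#' @return Coverage fraction (e.g. 0.036 for 7.98e8 bases of a 2.2e10 bp
#'   genome).
#' @export
genome_equivalents <- function(total_read_bases, genome_size) {
  if (genome_size <= 0) stop("genome size must be positive")
  if (total_read_bases <= 0) stop("total read bases must be positive")
  total_read_bases / genome_size
}

#' Abundance estimate of a repeat element from read-match counts
#'
#' The core bookkeeping of the element-abundance table: the genome
#' portion of an element is the fraction of reads matching it; total bp,
#' copy number and per-chromosome averages follow from the configured
#' genome size and chromosome count.
#'
#' @param element_name Element label.
#' @param n_matching_reads Number of reads matching the element.
#' @param pool_size Total reads in the pool.
#' @param element_length_bp Estimated element length.
#' @param config An [analysis_config()] supplying `genome_size_bp` and
#'   `n_chromosomes`.
#' @return An `abundance_estimate` with fields `genome_portion`,
#'   `total_bp`, `copies`, `per_chromosome_copies`, `per_chromosome_bp`
#'   (all unrounded).
#' @export
abundance_estimate <- function(element_name, n_matching_reads, pool_size,
                               element_length_bp,
                               config = analysis_config()) {
  if (pool_size <= 0) stop("empty read pool")
  if (n_matching_reads < 0 || n_matching_reads > pool_size)
    stop("n_matching_reads must be between 0 and pool_size")
  portion <- n_matching_reads / pool_size
  total_bp <- portion * config$genome_size_bp
  copies <- total_bp / element_length_bp
  structure(list(element_name = element_name,
                 n_matching_reads = n_matching_reads,
                 pool_size = pool_size,
                 genome_portion = portion,
                 element_length_bp = element_length_bp,
                 total_bp = total_bp,
                 copies = copies,
                 per_chromosome_copies = copies / config$n_chromosomes,
                 per_chromosome_bp = total_bp / config$n_chromosomes,
                 config = config),
            class = "abundance_estimate")
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat(sprintf("Element %s\n", x$element_name))
  cat(sprintf("  matching reads:   %s of %s\n",
              format(x$n_matching_reads, big.mark = ","),
              format(x$pool_size, big.mark = ",")))
  cat(sprintf("  genome portion:   %.3g%%\n", 100 * x$genome_portion))
  cat(sprintf("  total bp:         %.2g\n", x$total_bp))
  cat(sprintf("  element length:   %d bp\n", as.integer(x$element_length_bp)))
  cat(sprintf("  copies in genome: %.2g\n", x$copies))
  invisible(x)
}

#' Quantify a repeat element's genome abundance from a read pool
#'
#' A read counts as matching when it has at least one local alignment to
#' the element consensus at or above `min_identity` covering at least
#' `min_read_coverage` of the read (read-count rule, matching the way
#' element tables count "No. WGS reads").
#'
#' @param reads A [read_set()].
#' @param consensus Element consensus sequence.
#' @param min_identity Identity cutoff (default 0.75).
#' @param config An [analysis_config()].
#' @param min_read_coverage Minimum fraction of the read covered by the
#'   alignment (default 0.9).
#' @param element_name Label for the estimate.
#' @return An `abundance_estimate`.
#' @export
quantify_element <- function(reads, consensus, min_identity = 0.75,
                             config = analysis_config(),
                             min_read_coverage = 0.9,
                             element_name = "element") {
  stopifnot(inherits(reads, "read_set"))
  consensus <- as_contig(consensus)
  if (nchar(consensus) < reads$read_length)
    stop("consensus shorter than the read length")
  min_len <- as.integer(ceiling(min_read_coverage * reads$read_length))
  hits <- align_read_set(reads, consensus, "consensus",
                         min_identity = min_identity, min_aln_len = min_len)
  ok <- (hits$read_end - hits$read_start) >= min_len
  n_match <- length(unique(hits$read_index[ok]))
  abundance_estimate(element_name, n_match, reads$n, nchar(consensus),
                     config)
}

#' Exact-motif abundance assay (telomeric repeat content)
#'
#' A read matches when it contains the motif or its reverse complement at
#' least once (counted once regardless of multiplicity).
#'
#' @param reads A [read_set()].
#' @param motif Motif string (default the plant telomere repeat
#'   `TTTAGGG`).
#' @param config An [analysis_config()].
#' @return An `abundance_estimate` with `element_length_bp` equal to the
#'   motif length.
#' @export
motif_assay <- function(reads, motif = "TTTAGGG",
                        config = analysis_config()) {
  stopifnot(inherits(reads, "read_set"))
  if (!is_dna_string(motif)) stop("empty motif")
  motif <- toupper(motif)
  if (nchar(motif) > reads$read_length)
    stop("motif longer than the read length")
  hit <- grepl(motif, reads$reads, fixed = TRUE) |
    grepl(revcomp(motif), reads$reads, fixed = TRUE)
  abundance_estimate(motif, sum(hit), reads$n, nchar(motif), config)
}

#' Base composition of sequences or a read pool
#'
#' @param x A DNA string, character vector, or [read_set()].
#' @return Named fractions `A`, `C`, `G`, `T` over non-N bases (summing
#'   to 1) plus `GC`.
#' @export
gc_content <- function(x) {
  if (inherits(x, "read_set")) x <- x$reads
  if (!length(x) || !any(nzchar(x))) stop("empty input")
  fr <- base_frequencies(toupper(x))
  c(fr, GC = unname(fr["C"] + fr["G"]))
}

#' Percentage of the genome represented by a base count
#'
#' @param bp Base pairs (>= 0).
#' @param config An [analysis_config()].
#' @return Percentage `100 * bp / genome_size_bp`.
#' @export
genome_fraction <- function(bp, config = analysis_config()) {
  if (bp < 0) stop("bp must be non-negative")
  100 * bp / config$genome_size_bp
}

#' Element-abundance report table
#'
#' One row per element with the raw and presentation-rounded abundance
#' fields (portions at 3 significant figures, copies and bp at 2).
#'
#' @param estimates List of `abundance_estimate`s.
#' @return data.frame.
#' @export
abundance_report <- function(estimates) {
  stopifnot(all(vapply(estimates, inherits, TRUE, "abundance_estimate")))
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(element = e$element_name,
               n_reads = e$n_matching_reads,
               pool_size = e$pool_size,
               genome_portion_pct = signif(100 * e$genome_portion, 3),
               total_bp = signif(e$total_bp, 2),
               element_length_bp = e$element_length_bp,
               copies = signif(e$copies, 2),
               per_chromosome_copies = signif(e$per_chromosome_copies, 2),
               per_chromosome_bp = signif(e$per_chromosome_bp, 2),
               stringsAsFactors = FALSE)
  }))
}
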