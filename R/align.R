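# Local alignment of fixed-length reads against contigs.  The scoring
# scheme is the discontiguous-megablast-style +1/-1 with gap open and
# extension both costing 2, i.e. a linear per-column gap cost.  Alignment
# stringency is expressed either as a minimum identity (default) or as a
# raw score threshold (compatibility mode).

#' Alignment scoring scheme
#'
#' @param match Match reward (> 0; default +1).
#' @param mismatch Mismatch penalty (< 0; default -1).
#' @param gap_open,gap_extend Positive per-gap-column costs (default 2/2;
#'   equal costs make the gap penalty linear per column).
#' @param word_size Seed word size; `NULL` (default) chooses 11 for
#'   high-stringency searches (identity >= 0.95) and 8 otherwise.
#' @return A `scoring_scheme` object.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -1L, gap_open = 2L,
                           gap_extend = 2L, word_size = NULL) {
  if (!(match > 0 && mismatch < 0))
    stop("require match > 0 > mismatch")
  if (gap_open != gap_extend)
    stop("only linear gap costs (gap_open == gap_extend) are supported")
  if (-gap_extend > mismatch)
    stop("gap cost must be at least as severe as a mismatch")
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 word_size = if (is.null(word_size)) NULL
                             else as.integer(word_size)),
            class = "scoring_scheme")
}

.word_for <- function(scoring, min_identity, min_score) {
  if (!is.null(scoring$word_size)) return(scoring$word_size)
  if (!is.null(min_identity) && min_identity >= 0.95) 11L else 8L
}

.check_cutoffs <- function(min_score, min_identity) {
  if (is.null(min_score) == is.null(min_identity))
    stop("give exactly one of min_score or min_identity")
  if (!is.null(min_score) && min_score < 1)
    stop("min_score must be at least 1")
  if (!is.null(min_identity) && (min_identity <= 0 || min_identity > 1))
    stop("min_identity must be in (0, 1]")
}

.finish_hits <- function(df, read_ids, contig_id) {
  df <- as.data.frame(df)
  df$read_id <- read_ids[df$read_index]
  df$contig_id <- rep(contig_id, nrow(df))
  df[, c("read_id", "contig_id", "contig_start", "contig_end",
         "read_start", "read_end", "strand", "score", "n_match",
         "n_mismatch", "n_gap", "identity", "read_index")]
}

#' Align a pool of reads against one contig
#'
#' Seed-and-extend local alignment of every read (both strands) against
#' the contig.  All locally optimal alignments meeting the cutoff are
#' returned; overlapping hits of the same read are collapsed to the
#' best-scoring one per locus (ties: leftmost start, then `+` strand).
#' Any full-length ungapped alignment at or above the cutoff whose
#' diagonal shares at least one exact seed word with the contig is
#' guaranteed to be found.
#'
#' @param reads A [read_set()] or character vector of reads.
#' @param contig Contig sequence (string) or a `read_fasta()` row.
#' @param contig_id Contig name used in the hit table.
#' @param scoring A [scoring_scheme()].
#' @param min_score Integer score cutoff (compatibility mode), or NULL.
#' @param min_identity Identity cutoff in (0, 1] (default mode), or NULL.
#' @param min_aln_len Minimum alignment columns for identity mode.
#' @param band Diagonal band half-width around seeds.
#' @return Hit table: one row per retained alignment, 0-based half-open
#'   contig coordinates, sorted by `contig_start`.
#' @export
align_read_set <- function(reads, contig, contig_id = "contig",
                           scoring = scoring_scheme(), min_score = NULL,
                           min_identity = NULL, min_aln_len = 30L,
                           band = 6L) {
  .check_cutoffs(min_score, min_identity)
  seqs <- if (inherits(reads, "read_set")) reads$reads else as.character(reads)
  ids <- if (inherits(reads, "read_set")) reads$ids
         else sprintf("read%06d", seq_along(seqs))
  contig <- as_contig(contig)
  word <- .word_for(scoring, min_identity, min_score)
  if (min(nchar(seqs)) < word)
    stop("read shorter than the seed word size (", word, ")")
  df <- align_reads_cpp(seqs, contig, word, scoring$match, scoring$mismatch,
                        scoring$gap_extend,
                        if (is.null(min_identity)) -1 else min_identity,
                        if (is.null(min_score)) NA_integer_
                        else as.integer(min_score),
                        as.integer(min_aln_len), as.integer(band))
  .finish_hits(df, ids, contig_id)
}

#' Find local alignments of one read against a contig
#'
#' Single-read convenience wrapper around [align_read_set()].
#'
#' @inheritParams align_read_set
#' @param read A single read sequence.
#' @param read_id Identifier used in the hit table.
#' @return Hit table (possibly empty), sorted by `contig_start`.
#' @examples
#' contig <- paste(rep("ACGTTGCA", 30), collapse = "")
#' find_hits(substr(contig, 101, 160), contig, min_identity = 0.99)
#' @export
find_hits <- function(read, contig, scoring = scoring_scheme(),
                      min_score = NULL, min_identity = NULL,
                      min_aln_len = 30L, read_id = "read1", band = 6L) {
  stopifnot(is_dna_string(read))
  align_read_set(stats::setNames(toupper(read), read_id), contig,
                 scoring = scoring, min_score = min_score,
                 min_identity = min_identity, min_aln_len = min_aln_len,
                 band = band)
}

#' Exhaustive Smith-Waterman oracle
#'
#' Full dynamic-programming local alignment of one read against a small
#' contig (both strands), enumerating all non-overlapping locally optimal
#' alignments at or above the cutoff.  This is the verification oracle
#' for [find_hits()]; it shares no code with the seeded path.
#'
#' @inheritParams find_hits
#' @param max_contig_bp Guard on contig size (default 10 kb).
#' @return Hit table sorted by `contig_start`.
#' @export
sw_oracle <- function(read, contig, scoring = scoring_scheme(),
                      min_score = NULL, min_identity = NULL,
                      min_aln_len = 30L, read_id = "read1",
                      max_contig_bp = 10000L) {
  .check_cutoffs(min_score, min_identity)
  contig <- as_contig(contig)
  if (nchar(contig) > max_contig_bp)
    stop("sw_oracle is restricted to contigs of at most ", max_contig_bp,
         " bp")
  df <- sw_oracle_cpp(toupper(read), contig, scoring$match, scoring$mismatch,
                      scoring$gap_extend,
                      if (is.null(min_identity)) -1 else min_identity,
                      if (is.null(min_score)) NA_integer_
                      else as.integer(min_score),
                      as.integer(min_aln_len))
  .finish_hits(df, read_id, "contig")
}

#' Minimum identity of a full-length ungapped hit at a score threshold
#'
#' Under +1/-1 scoring, a full-length ungapped alignment of a read with
#' `m` mismatches scores `read_length - 2 m`; the worst identity
#' compatible with a score is therefore `(read_length - m) / read_length`
#' with `m = floor((read_length - score) / 2)`.
#'
#' @param score Score threshold (<= read_length).
#' @param read_length Read length in bp.
#' @return Minimum identity fraction.
#' @examples
#' identity_for_score(55, 60)  # ~0.967
#' identity_for_score(24, 60)  # 0.70
#' @export
identity_for_score <- function(score, read_length) {
  stopifnot(score <= read_length)
  m <- floor((read_length - score) / 2)
  (read_length - m) / read_length
}
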