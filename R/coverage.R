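# Per-base coverage maps at identity stringencies, repetitive/single-copy
# classification, and depth-ratio copy-number estimation.

coverage_map_from_depth <- function(depth, contig_id = "contig",
                                    threshold = NA_real_,
                                    genome_coverage = NA_real_) {
  structure(list(contig_id = contig_id, depth = as.integer(depth),
                 threshold = threshold, genome_coverage = genome_coverage),
            class = "coverage_map")
}

#' Build a per-base coverage map from alignment hits
#'
#' `depth[p]` counts the alignments whose contig footprint contains
#' position `p`.  A read aligning twice to the contig contributes twice,
#' the literal reading of "hits per base pair".
#'
#' @param hits Hit table (from [align_read_set()]), already filtered to
#'   this contig and stringency.
#' @param contig_length Contig length in bp.
#' @param contig_id Contig name.
#' @param threshold Identity stringency recorded on the map.
#' @param genome_coverage Genome-equivalent coverage of the read pool.
#' @return A `coverage_map`.
#' @export
build_coverage_map <- function(hits, contig_length, contig_id = "contig",
                               threshold = NA_real_,
                               genome_coverage = NA_real_) {
  contig_length <- as.integer(contig_length)
  depth <- integer(contig_length)
  if (nrow(hits)) {
    if (any(hits$contig_start < 0) || any(hits$contig_end > contig_length))
      stop("hit out of contig bounds")
    tab_s <- tabulate(hits$contig_start + 1L, contig_length + 1L)
    tab_e <- tabulate(hits$contig_end + 1L, contig_length + 1L)
    depth <- cumsum(tab_s - tab_e)[seq_len(contig_length)]
  }
  coverage_map_from_depth(depth, contig_id, threshold, genome_coverage)
}

#' Coverage maps of one contig at several identity stringencies
#'
#' Aligns the pool once at the laxest stringency and derives one map per
#' threshold by filtering hits on alignment identity, so maps from the
#' same pool are pointwise ordered by construction.
#'
#' @param reads A [read_set()].
#' @param contig Contig sequence.
#' @param contig_id Contig name.
#' @param thresholds Identity thresholds (default 0.75 and 0.99).
#' @param genome_coverage Genome-equivalent coverage of the pool
#'   (defaults to `reads$coverage`).
#' @param min_aln_len Minimum alignment columns.
#' @param scoring A [scoring_scheme()].
#' @return Named list of `coverage_map`s, one per threshold.
#' @export
coverage_maps <- function(reads, contig, contig_id = "contig",
                          thresholds = c(0.75, 0.99),
                          genome_coverage = NULL, min_aln_len = 30L,
                          scoring = scoring_scheme()) {
  stopifnot(inherits(reads, "read_set"))
  genome_coverage <- genome_coverage %||% reads$coverage
  contig <- as_contig(contig)
  thresholds <- sort(thresholds)
  hits <- align_read_set(reads, contig, contig_id, scoring = scoring,
                         min_identity = thresholds[1L],
                         min_aln_len = min_aln_len)
  out <- lapply(thresholds, function(t) {
    build_coverage_map(hits[hits$identity >= t, , drop = FALSE],
                       nchar(contig), contig_id, threshold = t,
                       genome_coverage = genome_coverage)
  })
  names(out) <- sprintf("t%g", thresholds)
  out
}

#' @export
print.coverage_map <- function(x, ...) {
  cat(sprintf("Coverage map of %s: %d bp", x$contig_id, length(x$depth)))
  if (!is.na(x$threshold)) cat(sprintf(", identity >= %g", x$threshold))
  cat(sprintf("\n  mean depth %.3f, max depth %d\n",
              mean(x$depth), max(x$depth)))
  invisible(x)
}

#' @export
plot.coverage_map <- function(x, window = 50L, ...) {
  wp <- window_profile(x, window)
  graphics::plot(wp$window_start, wp$mean_depth, type = "h",
                 xlab = sprintf("%s position (bp)", x$contig_id),
                 ylab = sprintf("mean hits/bp (%d bp windows)", window),
                 ...)
  invisible(wp)
}

#' Fraction of contig positions classified repetitive
#'
#' A position is repetitive when its alignment depth is at least
#' `min_depth` (default 2: under single-copy coverage of ~0.036x the
#' chance of two independent reads stacking is negligible, while any
#' locus with tens of genomic copies is almost surely covered twice).
#'
#' @param covmap A `coverage_map`.
#' @param min_depth Minimum depth to call a position repetitive (>= 1).
#' @return Fraction in `[0, 1]`.
#' @export
repetitive_fraction <- function(covmap, min_depth = 2L) {
  stopifnot(inherits(covmap, "coverage_map"))
  if (min_depth < 1) stop("min_depth must be at least 1")
  mean(covmap$depth >= min_depth)
}

#' Merged repetitive segments of a coverage map
#'
#' @inheritParams repetitive_fraction
#' @return data.frame of 0-based half-open intervals (`contig_id`,
#'   `start`, `end`, `name`), suitable for [write_bed()].
#' @export
repetitive_segments <- function(covmap, min_depth = 2L) {
  stopifnot(inherits(covmap, "coverage_map"))
  r <- rle(covmap$depth >= min_depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(contig_id = covmap$contig_id, start = starts[keep],
             end = ends[keep],
             name = sprintf("rep_ge%d", min_depth),
             stringsAsFactors = FALSE)
}

#' Genome-wide copy number of a contig interval
#'
#' Mean alignment depth over the interval divided by the
#' genome-equivalent coverage of the read pool.
#'
#' @param covmap A `coverage_map` with `genome_coverage` set.
#' @param start,end 0-based half-open interval on the contig.
#' @return A `copy_number_estimate`: `mean_depth`, `genome_coverage`,
#'   `copies`.
#' @export
copy_number <- function(covmap, start, end) {
  stopifnot(inherits(covmap, "coverage_map"))
  if (end <= start) stop("zero-length interval")
  if (start < 0 || end > length(covmap$depth))
    stop("interval outside contig bounds")
  if (is.na(covmap$genome_coverage) || covmap$genome_coverage <= 0)
    stop("copy number undefined: genome_coverage is zero or unknown")
  md <- mean(covmap$depth[(start + 1L):end])
  structure(list(contig_id = covmap$contig_id, start = start, end = end,
                 mean_depth = md, genome_coverage = covmap$genome_coverage,
                 copies = md / covmap$genome_coverage),
            class = "copy_number_estimate")
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf(
    "Copy number of %s:%d-%d: mean depth %.3f / coverage %.4gx = %.1f copies\n",
    x$contig_id, x$start, x$end, x$mean_depth, x$genome_coverage, x$copies))
  invisible(x)
}

#' Windowed mean-depth profile of a coverage map
#'
#' @param covmap A `coverage_map`.
#' @param window Window size in bp (default 50); the last window may be
#'   short and is averaged over its actual positions.
#' @return data.frame with `window_start`, `window_end` (0-based
#'   half-open) and `mean_depth`.
#' @export
window_profile <- function(covmap, window = 50L) {
  stopifnot(inherits(covmap, "coverage_map"))
  window <- as.integer(window)
  if (window < 1) stop("window must be >= 1")
  L <- length(covmap$depth)
  idx <- rep(seq_len(ceiling(L / window)), each = window)[seq_len(L)]
  means <- as.numeric(tapply(covmap$depth, idx, mean))
  starts <- (seq_along(means) - 1L) * window
  data.frame(window_start = starts,
             window_end = pmin(starts + window, L),
             mean_depth = means)
}
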