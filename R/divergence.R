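# Identity-binned repeat-divergence profiling: sample regions of a
# genome, align genome-equivalent fixed-length read sets to them, and
# summarize what fraction of the sampled positions is covered best by an
# alignment in each nucleotide-identity bin, replicated and averaged.

#' Divergence-profiling configuration
#'
#' Defaults follow the cross-genome comparison protocol: 60 bp reads at
#' 0.036 genome equivalents aligned to 920,000 bp of randomly selected
#' regions, repeat coverage split into 70-84%, 85-97% and 98-100%
#' identity bins, averaged over 10 replicates.
#'
#' @param read_length_bp Read length (default 60).
#' @param coverage Genome-equivalent coverage drawn per replicate
#'   (default 0.036).
#' @param region_total_bp Total sampled region size (default 920,000).
#' @param region_size_bp Size of each sampled piece (default 10 kb).
#' @param bins Matrix-like list of identity bins as `c(lower, upper)`
#'   fractions; half-open below, closed at 1.
#' @param replicates Number of replicates (default 10).
#' @param min_identity Alignment floor (default 0.70).
#' @param min_aln_len Minimum alignment columns (default 45).
#' @param error_rate Read error rate for simulated pools (default 0).
#' @param seed Integer seed.
#' @return A `divergence_config`.
#' @export
divergence_config <- function(read_length_bp = 60L, coverage = 0.036,
                              region_total_bp = 920000,
                              region_size_bp = 10000L,
                              bins = list(c(0.70, 0.85), c(0.85, 0.98),
                                          c(0.98, 1.00)),
                              replicates = 10L, min_identity = 0.70,
                              min_aln_len = 45L, error_rate = 0,
                              seed = 1L) {
  lows <- vapply(bins, `[`, 1, 1L)
  highs <- vapply(bins, `[`, 1, 2L)
  if (any(lows >= highs) || any(diff(lows) <= 0) ||
      any(highs[-length(highs)] != lows[-1L]))
    stop("bins must be disjoint, ordered and contiguous")
  if (any(lows <= 0) || any(highs > 1))
    stop("bins must lie within (0, 1]")
  structure(list(read_length_bp = as.integer(read_length_bp),
                 coverage = coverage,
                 region_total_bp = as.numeric(region_total_bp),
                 region_size_bp = as.integer(region_size_bp),
                 bins = bins, replicates = as.integer(replicates),
                 min_identity = min_identity,
                 min_aln_len = as.integer(min_aln_len),
                 error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "divergence_config")
}

#' Sample non-overlapping regions of a genome
#'
#' Uniformly placed, non-overlapping pieces of `region_size_bp` (the last
#' piece may be shorter) totalling exactly `total_bp`; deterministic per
#' seed.
#'
#' @param genome_length Genome length in bp.
#' @param total_bp Total region size to sample.
#' @param region_size_bp Piece size (default 10 kb).
#' @param seed Integer seed.
#' @return data.frame of 0-based half-open intervals `start`, `end`.
#' @export
sample_regions <- function(genome_length, total_bp,
                           region_size_bp = 10000L, seed = 1L) {
  if (total_bp > genome_length)
    stop("infeasible packing: total_bp exceeds the genome length")
  n <- ceiling(total_bp / region_size_bp)
  lens <- rep(region_size_bp, n)
  lens[n] <- total_bp - (n - 1L) * region_size_bp
  free <- genome_length - total_bp
  set.seed(derive_seed(seed, "regions"))
  gaps <- if (free == 0) rep(0, n + 1L) else {
    cuts <- sort(stats::runif(n))
    g <- floor(diff(c(0, cuts, 1)) * free)
    g[n + 1L] <- g[n + 1L] + (free - sum(g))
    g
  }
  starts <- cumsum(gaps[seq_len(n)]) + c(0, cumsum(lens))[seq_len(n)]
  data.frame(start = starts, end = starts + lens)
}

#' Chop long sequences into consecutive fixed-length reads
#'
#' Non-overlapping consecutive pieces per sequence; trailing remainders
#' shorter than the read length are discarded.
#'
#' @param sequences Character vector of sequences (or `read_fasta()`
#'   output).
#' @param read_length_bp Piece length (default 60).
#' @return A [read_set()].
#' @export
chop_reads <- function(sequences, read_length_bp = 60L) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  L <- as.integer(read_length_bp)
  reads <- unlist(lapply(sequences, function(s) {
    k <- nchar(s) %/% L
    if (k == 0L) return(character(0))
    substring(s, (seq_len(k) - 1L) * L + 1L, seq_len(k) * L)
  }), use.names = FALSE)
  if (!length(reads)) stop("no sequence is as long as the read length")
  read_set(reads)
}

#' Identity-binned repeat-divergence profile of a genome
#'
#' Per replicate: draw a read pool at the configured coverage, sample
#' regions, align the pool to each region at the identity floor, and
#' assign every region position to the identity bin of its best-identity
#' covering alignment (positions with no alignment count as unaligned).
#' Replicates are averaged.
#'
#' @param truth A `genome_truth` (or single DNA string).
#' @param config A [divergence_config()].
#' @param reads Optional externally supplied [read_set()] reused for every
#'   replicate (e.g. from [chop_reads()]); otherwise pools are simulated
#'   per replicate.
#' @return An `identity_bin_profile`: per-replicate bin fractions,
#'   means and SDs, and the config.
#' @export
profile_divergence <- function(truth, config = divergence_config(),
                               reads = NULL) {
  genome <- if (inherits(truth, "genome_truth")) truth$sequences[[1L]]
            else as_contig(truth)
  G <- nchar(genome)
  if (config$region_total_bp > G)
    stop("region_total_bp exceeds the genome length")
  nb <- length(config$bins)
  per_rep <- matrix(0, nrow = config$replicates, ncol = nb + 1L,
                    dimnames = list(NULL, c(vapply(config$bins, function(b)
                      sprintf("id%02.0f_%03.0f", 100 * b[1L], 100 * b[2L]),
                      ""), "unaligned")))
  for (r in seq_len(config$replicates)) {
    rseed <- derive_seed(config$seed, sprintf("divrep%03d", r))
    pool <- if (is.null(reads)) {
      simulate_reads(truth, config$read_length_bp, config$coverage,
                     config$error_rate, seed = rseed)
    } else reads
    regions <- sample_regions(G, config$region_total_bp,
                              config$region_size_bp, seed = rseed + 1L)
    counts <- numeric(nb)
    total <- 0
    for (i in seq_len(nrow(regions))) {
      rs <- regions$start[i]; re <- regions$end[i]
      contig <- substr(genome, rs + 1L, re)
      hits <- align_read_set(pool, contig,
                             min_identity = config$min_identity,
                             min_aln_len = config$min_aln_len)
      best <- bin_cover_cpp(nchar(contig), hits$contig_start,
                            hits$contig_end, hits$identity)
      for (b in seq_len(nb)) {
        lo <- config$bins[[b]][1L]; hi <- config$bins[[b]][2L]
        counts[b] <- counts[b] +
          sum(best >= lo & (best < hi | (hi >= 1 & best >= 1)))
      }
      total <- total + nchar(contig)
    }
    per_rep[r, seq_len(nb)] <- counts / total
    per_rep[r, nb + 1L] <- 1 - sum(counts / total)
  }
  structure(list(per_replicate = per_rep,
                 mean = colMeans(per_rep),
                 sd = apply(per_rep, 2L, stats::sd),
                 config = config),
            class = "identity_bin_profile")
}

#' @export
print.identity_bin_profile <- function(x, ...) {
  cat(sprintf("Identity-bin profile (%d replicates):\n",
              nrow(x$per_replicate)))
  for (i in seq_along(x$mean))
    cat(sprintf("  %-10s %6.2f%%  (sd %.2f)\n", names(x$mean)[i],
                100 * x$mean[i], 100 * x$sd[i]))
  invisible(x)
}

#' @export
plot.identity_bin_profile <- function(x, ...) {
  graphics::barplot(100 * x$mean, ylab = "% of sampled positions", ...)
  invisible(x)
}
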