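# Contig-level discovery of additional repeat classes: direct-repeat
# (candidate LTR) pairs, tandem arrays, simple/low-complexity repeats,
# and long nongenic ORF elements.

.exon_rows <- function(annotations) {
  if (is.null(annotations)) return(NULL)
  stopifnot(is.data.frame(annotations))
  if ("type" %in% names(annotations)) {
    ex <- annotations[annotations$type %in% c("exon", "CDS"), , drop = FALSE]
    if (nrow(ex)) return(ex)
  }
  annotations
}

.overlaps_any <- function(start, end, rows) {
  if (is.null(rows) || nrow(rows) == 0L) return(rep(FALSE, length(start)))
  vapply(seq_along(start), function(i) {
    any(start[i] < rows$end & rows$start < end[i])
  }, TRUE)
}

#' Find direct-repeat pairs (candidate LTR pairs) within a contig
#'
#' Ungapped word-seeded self-comparison of the contig (main diagonal
#' excluded).  Same-strand local alignments of at least `min_len` whose
#' two copies span at least `min_span` are reported as candidate
#' terminal-repeat pairs of uncharacterized LTR retrotransposons.  When
#' gene annotations are supplied, pairs with either repeat overlapping an
#' exon are dropped (the "putatively noncoding" rule).
#'
#' @param contig Contig sequence.
#' @param min_len Minimum repeat length (default 100 bp).
#' @param min_span Minimum span from the start of the first repeat to the
#'   end of the second (default 500 bp).
#' @param min_identity Reporting floor on pair identity (default 0.50).
#' @param annotations Optional annotation data.frame (from
#'   [read_gff3()]).
#' @param contig_id Contig name for the output.
#' @return data.frame of pairs: `start1`, `end1`, `start2`, `end2`
#'   (0-based half-open, canonical order by start), `length`,
#'   `identity`, `span_bp`.
#' @export
find_direct_repeats <- function(contig, min_len = 100L, min_span = 500L,
                                min_identity = 0.50, annotations = NULL,
                                contig_id = "contig") {
  contig <- as_contig(contig)
  if (nchar(contig) < min_span)
    stop("contig shorter than min_span")
  sa <- self_align_cpp(contig, 11L, as.integer(min_len), min_identity,
                       20L, 64L)
  if (nrow(sa)) {
    sa$span_bp <- sa$end2 - sa$start1
    sa <- sa[sa$span_bp >= min_span, , drop = FALSE]
  }
  if (nrow(sa)) {
    ex <- .exon_rows(annotations)
    coding <- .overlaps_any(sa$start1, sa$end1, ex) |
      .overlaps_any(sa$start2, sa$end2, ex)
    sa <- sa[!coding, , drop = FALSE]
  }
  if (!nrow(sa))
    return(data.frame(contig_id = character(0), start1 = integer(0),
                      end1 = integer(0), start2 = integer(0),
                      end2 = integer(0), length = integer(0),
                      identity = numeric(0), span_bp = integer(0),
                      stringsAsFactors = FALSE))
  out <- data.frame(contig_id = contig_id, start1 = sa$start1,
                    end1 = sa$end1, start2 = sa$start2, end2 = sa$end2,
                    length = sa$length, identity = sa$identity,
                    span_bp = sa$span_bp, stringsAsFactors = FALSE)
  out[order(out$start1, out$start2), , drop = FALSE]
}

#' Find tandem arrays of 5-200 bp units
#'
#' Lag-correlation detector: for each candidate period, lag-p matches are
#' smoothed in sliding windows; qualifying runs are merged into arrays
#' and each array is reported at the smallest period that explains it
#' (periods that are multiples of an accepted smaller period are
#' suppressed by overlap).  The consensus unit is the column majority
#' over unit-aligned copies.
#'
#' @param contig Contig sequence.
#' @param period_range Unit-size bounds (default 5-200 bp).
#' @param min_copies Minimum (fractional) copies per array (default 2).
#' @param min_fraction_match Minimum lag-match fraction (default 0.8).
#' @param contig_id Contig name for the output.
#' @return data.frame of arrays: `start`, `end` (0-based half-open),
#'   `period_bp`, `copy_number`, `consensus_unit`, `percent_match`.
#' @export
find_tandem_repeats <- function(contig, period_range = c(5L, 200L),
                                min_copies = 2, min_fraction_match = 0.8,
                                contig_id = "contig") {
  contig <- as_contig(contig)
  x <- utf8ToInt(contig)
  n <- length(x)
  res <- list()
  occupied_start <- integer(0)
  occupied_end <- integer(0)
  for (p in seq(period_range[1L], period_range[2L])) {
    w <- max(p, 12L)            # smoothing window: >= 12 bp curbs noise
    if (n < p + w) break
    m <- as.integer(x[seq_len(n - p)] == x[seq_len(n - p) + p])
    cs <- c(0L, cumsum(m))
    nf <- n - p - w + 1L
    if (nf < 1L) next
    frac <- (cs[(w + 1L):(n - p + 1L)] - cs[seq_len(nf)]) / w
    ok <- frac >= min_fraction_match
    if (!any(ok)) next
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i0 <- starts[k]                  # 1-based index into frac
      j0 <- ends[k]
      a <- i0 - 1L                     # 0-based array start
      b <- (j0 - 1L) + w + p           # 0-based half-open array end
      len <- b - a
      if (len / p < min_copies) next
      # suppress arrays explained by an accepted smaller period
      ov <- sum(pmax(0, pmin(b, occupied_end) - pmax(a, occupied_start)))
      if (ov > 0.5 * len) next
      # consensus unit: column majority over complete units
      ncopy <- floor(len / p)
      unitmat <- matrix(x[a + seq_len(ncopy * p)], nrow = p)
      unit <- intToUtf8(apply(unitmat, 1L, function(col) {
        tb <- sort(table(col), decreasing = TRUE)
        as.integer(names(tb)[1L])
      }))
      pm <- mean(m[(a + 1L):(b - p)])
      res[[length(res) + 1L]] <- data.frame(
        contig_id = contig_id, start = a, end = b, period_bp = p,
        copy_number = len / p, consensus_unit = unit,
        percent_match = pm, stringsAsFactors = FALSE)
      occupied_start <- c(occupied_start, a)
      occupied_end <- c(occupied_end, b)
    }
  }
  if (!length(res))
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), period_bp = integer(0),
                      copy_number = numeric(0),
                      consensus_unit = character(0),
                      percent_match = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out[order(out$start), , drop = FALSE]
}

#' Find simple/low-complexity repeats
#'
#' Windows with base-frequency Shannon entropy below `entropy_bits`, or
#' containing a mono-/di-/tri-/tetra-nucleotide unit repeated at least
#' 8/6/5/5 times, merged into maximal intervals.
#'
#' @param contig Contig sequence.
#' @param window Entropy window size (default 64 bp).
#' @param entropy_bits Entropy threshold (default 1.0 bits).
#' @param unit_max Largest short-unit size checked (default 4).
#' @param contig_id Contig name for the output.
#' @return data.frame of intervals `start`, `end`, `label`.
#' @export
find_simple_repeats <- function(contig, window = 64L, entropy_bits = 1.0,
                                unit_max = 4L, contig_id = "contig") {
  contig <- as_contig(contig)
  x <- utf8ToInt(contig)
  n <- length(x)
  if (n < window) stop("contig shorter than the entropy window")
  mark <- logical(n)
  labels <- character(n)
  # entropy rule over half-overlapping windows
  codes <- utf8ToInt("ACGTN")
  csum <- sapply(codes[1:4], function(b) c(0L, cumsum(x == b)))
  step <- max(1L, window %/% 2L)
  for (s in seq(1L, n - window + 1L, by = step)) {
    cnt <- csum[s + window, ] - csum[s, ]
    tot <- sum(cnt)
    if (tot == 0L) next
    pr <- cnt[cnt > 0] / tot
    h <- -sum(pr * log2(pr))
    if (h < entropy_bits) {
      mark[s:(s + window - 1L)] <- TRUE
      labels[s:(s + window - 1L)] <- "low_entropy"
    }
  }
  # exact short-unit runs
  reps_req <- c(8L, 6L, 5L, 5L)
  unit_names <- c("mono", "di", "tri", "tetra")
  for (u in seq_len(unit_max)) {
    if (n <= u) next
    m <- x[seq_len(n - u)] == x[seq_len(n - u) + u]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    need <- (reps_req[u] - 1L) * u
    for (k in which(r$values & r$lengths >= need)) {
      a <- starts[k]
      b <- ends[k] + u
      mark[a:b] <- TRUE
      labels[a:b] <- ifelse(nzchar(labels[a:b]), labels[a:b], unit_names[u])
    }
  }
  if (!any(mark))
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), label = character(0),
                      stringsAsFactors = FALSE))
  r <- rle(mark)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(contig_id = contig_id, start = starts[keep], end = ends[keep],
             label = vapply(which(keep), function(k) {
               labels[starts[k] + 1L]
             }, ""), stringsAsFactors = FALSE)
}

# ORFs (ATG..stop, length multiple of 3 incl. the stop codon) on one strand
.orfs_one_strand <- function(seq, min_len) {
  n <- nchar(seq)
  out <- list()
  stops <- c("TAA", "TAG", "TGA")
  for (f in 0:2) {
    pos <- seq(f + 1L, n - 2L, by = 3L)
    if (!length(pos)) next
    codons <- substring(seq, pos, pos + 2L)
    is_stop <- codons %in% stops
    is_atg <- codons == "ATG"
    prev_stop <- 0L  # index into codon vector of last stop (0 = none)
    i <- 1L
    while (i <= length(codons)) {
      if (is_stop[i]) {
        cand <- which(is_atg[(prev_stop + 1L):i])
        if (length(cand)) {
          a <- prev_stop + cand[1L]
          len <- (i - a + 1L) * 3L
          if (len >= min_len)
            out[[length(out) + 1L]] <- c(start = pos[a] - 1L,
                                         end = pos[i] + 2L, frame = f + 1L,
                                         length = len)
        }
        prev_stop <- i
      }
      i <- i + 1L
    }
  }
  out
}

#' Find long nongenic ORF elements
#'
#' All open reading frames (both strands, standard code, ATG to stop) of
#' at least `min_len` bp; ORFs overlapping an annotated gene are dropped
#' and only the longest ORF of each overlapping cluster is reported.
#' When a coverage map is supplied, ORFs with at least half their length
#' in repetitive positions are flagged.
#'
#' @param contig Contig sequence.
#' @param gene_annotations Optional annotation data.frame (from
#'   [read_gff3()]); rows of any type count as genic.
#' @param covmap Optional `coverage_map` for the repetitive flag.
#' @param min_len Minimum ORF length in bp (default 240).
#' @param min_depth Repetitive depth rule for the flag (default 2).
#' @param contig_id Contig name for the output.
#' @return data.frame: `start`, `end` (0-based half-open, stop codon
#'   included), `strand`, `frame`, `length`,
#'   `overlaps_repetitive_coverage`.
#' @export
find_orf_elements <- function(contig, gene_annotations = NULL,
                              covmap = NULL, min_len = 240L,
                              min_depth = 2L, contig_id = "contig") {
  contig <- as_contig(contig)
  n <- nchar(contig)
  fw <- .orfs_one_strand(contig, min_len)
  rv <- .orfs_one_strand(revcomp(contig), min_len)
  rows <- list()
  for (o in fw)
    rows[[length(rows) + 1L]] <- data.frame(
      start = o[["start"]], end = o[["end"]], strand = "+",
      frame = o[["frame"]], length = o[["length"]],
      stringsAsFactors = FALSE)
  for (o in rv)
    rows[[length(rows) + 1L]] <- data.frame(
      start = n - o[["end"]], end = n - o[["start"]], strand = "-",
      frame = -o[["frame"]], length = o[["length"]],
      stringsAsFactors = FALSE)
  empty <- data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      frame = integer(0), length = integer(0),
                      overlaps_repetitive_coverage = logical(0),
                      stringsAsFactors = FALSE)
  if (!length(rows)) return(empty)
  df <- do.call(rbind, rows)
  genic <- NULL
  if (!is.null(gene_annotations)) {
    if (!is.data.frame(gene_annotations) ||
        !all(c("start", "end") %in% names(gene_annotations)))
      stop("malformed annotation: need start/end columns")
    genic <- gene_annotations
  }
  df <- df[!.overlaps_any(df$start, df$end, genic), , drop = FALSE]
  if (!nrow(df)) return(empty)
  # keep the longest ORF per overlapping cluster
  df <- df[order(df$start, df$end), , drop = FALSE]
  cluster <- integer(nrow(df))
  cid <- 1L
  cur_end <- df$end[1L]
  cluster[1L] <- 1L
  for (i in seq_len(nrow(df))[-1L]) {
    if (df$start[i] < cur_end) {
      cluster[i] <- cid
      cur_end <- max(cur_end, df$end[i])
    } else {
      cid <- cid + 1L
      cluster[i] <- cid
      cur_end <- df$end[i]
    }
  }
  keep <- unlist(lapply(split(seq_len(nrow(df)), cluster), function(ix) {
    ix[order(-df$length[ix], df$start[ix], df$strand[ix])[1L]]
  }), use.names = FALSE)
  df <- df[sort(keep), , drop = FALSE]
  df$overlaps_repetitive_coverage <- if (!is.null(covmap)) {
    stopifnot(inherits(covmap, "coverage_map"))
    rep_pos <- covmap$depth >= min_depth
    vapply(seq_len(nrow(df)), function(i) {
      mean(rep_pos[(df$start[i] + 1L):df$end[i]]) >= 0.5
    }, TRUE)
  } else NA
  df <- cbind(data.frame(contig_id = contig_id, stringsAsFactors = FALSE), df)
  rownames(df) <- NULL
  df
}

#' Per-contig summary of additional repeat features
#'
#' Counts of tandem arrays, direct-repeat pairs and nongenic ORF elements
#' found on a contig.
#'
#' @param contig Contig sequence.
#' @param annotations Optional annotation data.frame.
#' @param contig_id Contig name.
#' @return One-row data.frame of feature counts.
#' @export
repeat_feature_summary <- function(contig, annotations = NULL,
                                   contig_id = "contig") {
  contig <- as_contig(contig)
  dr <- find_direct_repeats(contig, annotations = annotations,
                            contig_id = contig_id)
  tr <- find_tandem_repeats(contig, contig_id = contig_id)
  sr <- find_simple_repeats(contig, contig_id = contig_id)
  orf <- find_orf_elements(contig, gene_annotations = annotations,
                           contig_id = contig_id)
  data.frame(contig_id = contig_id, length_bp = nchar(contig),
             tandem_repeats = nrow(tr), direct_repeat_pairs = nrow(dr),
             simple_repeats = nrow(sr), orf_elements = nrow(orf),
             stringsAsFactors = FALSE)
}
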