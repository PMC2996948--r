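# Standard-format I/O: FASTA/FASTQ via Biostrings, GFF3 via rtracklayer,
# plus the .sgr and BED6 flat writers.  Internal coordinates are 0-based
# half-open everywhere; GFF3 and .sgr are converted at the boundary.

#' Read a FASTA file of contigs
#'
#' Sequences are uppercased and RNA `U` is mapped to `T`; characters
#' outside `A/C/G/T/N/U` are rejected, as are duplicate record ids and
#' empty records.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `sequence`, `description`,
#'   in file order.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">x demo", "acgt"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  hdr <- names(set)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  if (any(!nzchar(id))) stop("empty record id in FASTA file: ", path)
  if (anyDuplicated(id))
    stop("duplicate sequence id in FASTA file: ",
         id[duplicated(id)][1])
  if (any(!nzchar(seqs)))
    stop("empty sequence record in FASTA file: ", id[!nzchar(seqs)][1])
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("illegal character in sequence of record ", id[bad][1])
  data.frame(id = unname(id), sequence = unname(seqs),
             description = unname(desc), stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param records A data.frame as returned by [read_fasta()], or a named
#'   character vector of sequences.
#' @param path Output path.
#' @param wrap Line width for wrapped sequence lines (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  if (is.character(records)) {
    if (is.null(names(records))) stop("sequence vector must be named")
    records <- data.frame(id = names(records), sequence = unname(records),
                          description = "", stringsAsFactors = FALSE)
  }
  if (nrow(records) == 0L) stop("no records to write")
  hdr <- ifelse(nzchar(records$description %||% ""),
                paste(records$id, records$description),
                records$id)
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = as.integer(wrap))
  invisible(path)
}

#' Read a fixed-length WGS read pool
#'
#' All reads in a pool must share one length; FASTQ qualities are parsed
#' but ignored downstream.
#'
#' @param path FASTA or FASTQ file of reads.
#' @param format `"fasta"` or `"fastq"`.
#' @return A [read_set()] object.
#' @export
read_reads <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read file not found: ", path)
  if (format == "fasta") {
    rec <- read_fasta(path)
    rs <- read_set(rec$sequence, ids = rec$id)
  } else {
    raw <- readLines(path)
    raw <- raw[nzchar(raw) | seq_along(raw) %% 4 != 1]
    n4 <- length(raw)
    if (n4 == 0L || n4 %% 4L != 0L ||
        !all(startsWith(raw[seq(1L, n4, 4L)], "@")) ||
        !all(startsWith(raw[seq(3L, n4, 4L)], "+")) ||
        !all(nchar(raw[seq(2L, n4, 4L)]) == nchar(raw[seq(4L, n4, 4L)])))
      stop("malformed FASTQ file ", path,
           ": records must be @header/sequence/+/quality quartets")
    set <- tryCatch(
      Biostrings::readBStringSet(path, format = "fastq"),
      error = function(e) stop("malformed FASTQ file ", path, ": ",
                               conditionMessage(e)))
    seqs <- chartr("U", "T", toupper(as.character(set)))
    rs <- read_set(unname(seqs), ids = sub("\\s.*$", "", names(set)))
  }
  rs
}

#' Construct a read set
#'
#' @param reads Character vector of equal-length reads.
#' @param ids Optional read identifiers (defaults to `read000001`...).
#' @param coverage Optional genome-equivalent coverage of the pool.
#' @param sources Optional data.frame of known source loci (simulated
#'   pools record `start`, `strand`, `n_errors`).
#' @return An object of class `read_set` with fields `reads`, `ids`, `n`,
#'   `read_length`, `total_bases`, `coverage`, `sources`.
#' @export
read_set <- function(reads, ids = NULL, coverage = NA_real_, sources = NULL) {
  if (length(reads) == 0L) stop("empty read pool")
  lens <- nchar(reads)
  if (any(lens != lens[1L])) {
    off <- which(lens != lens[1L])[1L]
    nm <- if (!is.null(ids)) ids[off] else paste0("read #", off)
    stop("mixed read lengths: ", nm, " has length ", lens[off],
         ", expected ", lens[1L])
  }
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  structure(
    list(reads = as.character(reads), ids = as.character(ids),
         n = length(reads), read_length = lens[1L],
         total_bases = as.numeric(length(reads)) * lens[1L],
         coverage = coverage, sources = sources),
    class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("Read set: %d reads x %d bp (%.3g bases total)\n",
              x$n, x$read_length, x$total_bases))
  if (!is.na(x$coverage))
    cat(sprintf("  genome-equivalent coverage: %.4gx\n", x$coverage))
  invisible(x)
}

#' Write a read pool to FASTA
#'
#' @param reads A [read_set()].
#' @param path Output path.
#' @param wrap Line wrap width.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path, wrap = 60L) {
  stopifnot(inherits(reads, "read_set"))
  write_fasta(stats::setNames(reads$reads, reads$ids), path, wrap = wrap)
}

#' Write a coverage map in .sgr format
#'
#' One line per contig position: `contig <TAB> position <TAB> depth`,
#' with 1-based, dense, ascending positions.
#'
#' @param covmap A `coverage_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sgr <- function(covmap, path) {
  stopifnot(inherits(covmap, "coverage_map"))
  if (length(covmap$depth) == 0L) stop("empty coverage map")
  df <- data.frame(contig = covmap$contig_id,
                   pos = seq_along(covmap$depth),
                   depth = as.integer(covmap$depth))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an .sgr coverage map
#'
#' @param path Path to a 3-column .sgr file.
#' @param threshold Optional identity threshold to record on the map.
#' @param genome_coverage Optional genome-equivalent coverage to record.
#' @return A `coverage_map`.
#' @export
read_sgr <- function(path, threshold = NA_real_, genome_coverage = NA_real_) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("contig", "pos", "depth"),
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty .sgr file: ", path)
  if (length(unique(df$contig)) != 1L)
    stop("multi-contig .sgr files are not supported: ", path)
  if (!identical(df$pos, seq_len(nrow(df))))
    stop("positions in .sgr file are not dense 1-based ascending: ", path)
  coverage_map_from_depth(df$depth, contig_id = df$contig[1L],
                          threshold = threshold,
                          genome_coverage = genome_coverage)
}

# ---- GFF3 <-> internal intervals ------------------------------------------

#' Read a GFF3 annotation file
#'
#' GFF3's 1-based inclusive coordinates are converted to the internal
#' 0-based half-open convention; the nine columns and all attributes are
#' preserved as data.frame columns.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `contig_id`, `source`, `type`,
#'   `start`, `end`, `score`, `strand`, `phase`, plus one column per
#'   attribute key.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    source = as.character(S4Vectors::mcols(gr)$source %||%
                            rep(NA_character_, length(gr))),
    type = as.character(S4Vectors::mcols(gr)$type %||%
                          rep(NA_character_, length(gr))),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    score = as.numeric(S4Vectors::mcols(gr)$score %||%
                         rep(NA_real_, length(gr))),
    strand = chartr("*", ".", as.character(GenomicRanges::strand(gr))),
    phase = as.character(S4Vectors::mcols(gr)$phase %||%
                           rep(NA_character_, length(gr))),
    stringsAsFactors = FALSE)
  extra <- S4Vectors::mcols(gr)
  extra <- extra[, setdiff(colnames(extra),
                           c("source", "type", "score", "phase")),
                 drop = FALSE]
  for (nm in colnames(extra)) {
    v <- extra[[nm]]
    if (methods::is(v, "List")) v <- vapply(v, function(e) {
      if (length(e) == 0) NA_character_ else paste(e, collapse = ",")
    }, character(1))
    df[[nm]] <- as.vector(v)
  }
  if (any(df$end < df$start)) stop("GFF3 record with end < start in ", path)
  df
}

#' Write intervals as GFF3
#'
#' @param intervals A data.frame with at least `contig_id`, `start`,
#'   `end` (0-based half-open); optional `source`, `type`, `score`,
#'   `strand`, `phase` and arbitrary attribute columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(intervals, path) {
  stopifnot(is.data.frame(intervals),
            all(c("contig_id", "start", "end") %in% names(intervals)))
  if (any(intervals$start < 0) || any(intervals$end <= intervals$start))
    stop("invalid interval: require 0 <= start < end")
  n <- nrow(intervals)
  strand <- intervals$strand %||% rep(".", n)
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$contig_id,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end),
    strand = chartr(".", "*", strand))
  meta <- intervals[, setdiff(names(intervals),
                              c("contig_id", "start", "end", "strand")),
                    drop = FALSE]
  if (!"type" %in% names(meta)) meta$type <- "region"
  if (!"source" %in% names(meta)) meta$source <- "repeatscape"
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(meta)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write intervals as BED6
#'
#' @param intervals Data.frame with `contig_id`, `start`, `end` and
#'   optional `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(is.data.frame(intervals),
            all(c("contig_id", "start", "end") %in% names(intervals)))
  n <- nrow(intervals)
  df <- data.frame(chrom = intervals$contig_id,
                   start = as.integer(intervals$start),
                   end = as.integer(intervals$end),
                   name = intervals$name %||% rep(".", n),
                   score = intervals$score %||% rep(0L, n),
                   strand = intervals$strand %||% rep(".", n))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an alignment hit table
#'
#' Tab-separated, BLAST outfmt-6-like column order.
#'
#' @param hits A hit table from [find_hits()] or [align_read_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  cols <- intersect(c("read_id", "contig_id", "contig_start", "contig_end",
                      "strand", "score", "identity"), names(hits))
  utils::write.table(hits[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
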