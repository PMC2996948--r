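# Permissive consensus assembly of abundant repeats from a low-coverage
# read pool.  At far-below-1x coverage no two reads truly overlap on the
# genome, but reads from different copies of one repeat family do overlap
# on the family consensus; the assembler exploits exactly that, producing
# majority-rule ("most common base at each position") consensi.

#' Assembly parameters
#'
#' @param k Seed k-mer size for selecting the most frequent word
#'   (default 16).
#' @param min_overlap_bp Minimum read-to-consensus overlap to recruit a
#'   read (default 20).
#' @param min_overlap_identity Minimum ungapped identity over the overlap
#'   (default 0.80; must exceed 0.5).
#' @param min_column_depth Reads that must support a consensus column to
#'   keep extending (default 5).
#' @param max_elements Number of elements to report (default 3).
#' @param low_complexity_filter Require seed k-mers to have base-frequency
#'   entropy of at least 1.5 bits (default TRUE).
#' @param max_consensus_bp Hard cap on consensus length (default 20 kb).
#' @param recruit_word Word size used to propose read-to-consensus
#'   offsets during recruitment (default 10: small enough that a read
#'   diverged ~10% from the growing consensus still shares an exact word
#'   within a minimal overlap).
#' @param seed Integer seed (the assembler itself is deterministic given
#'   the pool order; the seed is recorded for provenance).
#' @return An `assembly_params` object.
#' @export
assembly_params <- function(k = 16L, min_overlap_bp = 20L,
                            min_overlap_identity = 0.80,
                            min_column_depth = 5L, max_elements = 3L,
                            low_complexity_filter = TRUE,
                            max_consensus_bp = 20000L, recruit_word = 10L,
                            seed = 1L) {
  if (min_overlap_identity <= 0.5 || min_overlap_identity > 1)
    stop("min_overlap_identity must be in (0.5, 1]")
  if (k < 8) stop("seed k-mer size must be at least 8")
  structure(list(k = as.integer(k),
                 min_overlap_bp = as.integer(min_overlap_bp),
                 min_overlap_identity = min_overlap_identity,
                 min_column_depth = as.integer(min_column_depth),
                 max_elements = as.integer(max_elements),
                 low_complexity_filter = isTRUE(low_complexity_filter),
                 max_consensus_bp = as.integer(max_consensus_bp),
                 recruit_word = as.integer(recruit_word),
                 seed = as.integer(seed)),
            class = "assembly_params")
}

#' Select the assembly seed k-mer
#'
#' The most frequent canonical (strand-collapsed) k-mer in the pool that
#' passes the low-complexity filter (Shannon entropy of its base
#' frequencies >= 1.5 bits); ties broken lexicographically.
#'
#' @param reads A [read_set()].
#' @param params An [assembly_params()].
#' @return The seed k-mer (character scalar).
#' @export
select_seed <- function(reads, params = assembly_params()) {
  stopifnot(inherits(reads, "read_set"))
  if (params$k > reads$read_length)
    stop("seed k-mer size exceeds the read length")
  res <- select_seed_cpp(reads$reads, params$k,
                         if (params$low_complexity_filter) 1.5 else 0)
  if (!nzchar(res$kmer))
    stop("no seed k-mer passes the low-complexity filter")
  attr(res$kmer, "count") <- res$count
  res$kmer
}

#' Greedy bidirectional consensus extension from a seed k-mer
#'
#' Reads overlapping the growing consensus by at least `min_overlap_bp`
#' columns at `min_overlap_identity` (either strand, ungapped) are
#' recruited and stacked at their best offset; each column takes the most
#' common base of its stack (ties go to the base with higher pool
#' frequency, then alphabetical order).  A direction stops when the next
#' column's stacked depth falls below `min_column_depth`.  Extension
#' through a tandem array is detected when the seed word recurs at a
#' short (<= 200 bp) phase; the consensus is then trimmed to one unit and
#' `tandem_period` is set.
#'
#' @param reads A [read_set()].
#' @param seed Seed k-mer (must occur in the pool).
#' @param params An [assembly_params()].
#' @return A `repeat_consensus`: `sequence`, `depth` (per-column),
#'   `supporting_read_count`, `reads` (recruited ids/offsets/strands),
#'   `structure` (`tandem_period`, `ltr_pair` after
#'   [detect_structure()]).
#' @export
extend_consensus <- function(reads, seed, params = assembly_params()) {
  stopifnot(inherits(reads, "read_set"), is_dna_string(seed))
  seed <- toupper(seed)
  present <- any(grepl(seed, reads$reads, fixed = TRUE)) ||
    any(grepl(revcomp(seed), reads$reads, fixed = TRUE))
  if (!present) stop("seed k-mer does not occur in the read pool")
  bf <- base_frequencies(utils::head(reads$reads, 5000L))
  res <- extend_consensus_cpp(reads$reads, seed, params$recruit_word,
                              params$min_overlap_bp,
                              params$min_overlap_identity,
                              params$min_column_depth,
                              params$max_consensus_bp, bf)
  structure(list(name = "element",
                 sequence = res$consensus,
                 depth = res$depth,
                 supporting_read_count = res$support,
                 reads = data.frame(read_id = reads$ids[res$read_id],
                                    offset = res$offset,
                                    strand = res$strand,
                                    stringsAsFactors = FALSE),
                 structure = list(
                   tandem_period = if (res$tandem_period > 0)
                     res$tandem_period else NULL,
                   ltr_pair = NULL)),
            class = "repeat_consensus")
}

#' @export
print.repeat_consensus <- function(x, ...) {
  cat(sprintf("Repeat consensus %s: %d bp, %d supporting reads\n",
              x$name, nchar(x$sequence), x$supporting_read_count))
  if (!is.null(x$structure$tandem_period))
    cat(sprintf("  tandem unit: %d bp\n", x$structure$tandem_period))
  lp <- x$structure$ltr_pair
  if (!is.null(lp))
    cat(sprintf("  terminal repeat pair: %d-%d / %d-%d (%.0f%% identity)\n",
                lp$start1, lp$end1, lp$start2, lp$end2, 100 * lp$identity))
  invisible(x)
}

#' Detect terminal-repeat pairs and tandem periodicity on a consensus
#'
#' Self-alignment of the consensus reports (a) a terminal direct-repeat
#' pair of at least 50 bp at 80% identity or better (`ltr_pair`), and
#' (b) a dominant autocorrelation period of 5-200 bp covering at least
#' 80% of the length (`tandem_period`).
#'
#' @param consensus A `repeat_consensus` or DNA string (>= 50 bp).
#' @return The `repeat_consensus` with its `structure` filled in (a bare
#'   structure list when given a string).
#' @export
detect_structure <- function(consensus) {
  obj <- NULL
  if (inherits(consensus, "repeat_consensus")) {
    obj <- consensus
    consensus <- obj$sequence
  }
  consensus <- as_contig(consensus)
  L <- nchar(consensus)
  if (L < 50) stop("consensus must be at least 50 bp")
  st <- list(ltr_pair = NULL, tandem_period = NULL)
  # tandem periodicity by lag autocorrelation
  x <- utf8ToInt(consensus)
  for (p in 5:min(200L, floor(L / 2))) {
    frac <- mean(x[seq_len(L - p)] == x[seq_len(L - p) + p])
    if (frac >= 0.8 && (L - p) / L >= 0.5) { st$tandem_period <- p; break }
  }
  # terminal direct-repeat pair by ungapped self-alignment
  sa <- self_align_cpp(consensus, 11L, 50L, 0.80, 20L, 64L)
  if (nrow(sa)) {
    term <- sa[sa$start1 <= 0.25 * L & sa$end2 >= 0.75 * L, , drop = FALSE]
    if (nrow(term)) {
      best <- term[order(-term$length, term$start1), ][1L, ]
      st$ltr_pair <- list(start1 = best$start1, end1 = best$end1,
                          start2 = best$start2, end2 = best$end2,
                          identity = best$identity)
    }
  }
  if (is.null(obj)) return(st)
  if (is.null(obj$structure$tandem_period))
    obj$structure$tandem_period <- st$tandem_period
  obj$structure$ltr_pair <- st$ltr_pair
  obj
}

#' Assemble the most abundant repeats from a read pool
#'
#' Iterates seed selection, consensus extension and read subtraction
#' (removing every read matching the new consensus at
#' `min_overlap_identity`) until `max_elements` elements are produced or
#' no usable seed remains.  Elements are ranked by supporting read count
#' and annotated with [detect_structure()]; when a `config` is supplied,
#' each element is quantified against the original pool with
#' [quantify_element()].
#'
#' @param reads A [read_set()].
#' @param params An [assembly_params()].
#' @param config Optional [analysis_config()] for abundance
#'   quantification.
#' @param min_identity Identity cutoff passed to [quantify_element()].
#' @return List of `repeat_consensus` objects (ranked); when quantified,
#'   each carries an `abundance` field and the list has an
#'   `abundance_report` attribute.
#' @export
assemble_top_repeats <- function(reads, params = assembly_params(),
                                 config = NULL, min_identity = 0.75) {
  stopifnot(inherits(reads, "read_set"))
  pool <- reads
  elements <- list()
  for (i in seq_len(params$max_elements)) {
    if (pool$n < params$min_column_depth) break
    sd <- tryCatch(select_seed(pool, params), error = function(e) NULL)
    if (is.null(sd)) break
    if (attr(sd, "count") < params$min_column_depth) break
    el <- extend_consensus(pool, sd, params)
    if (el$supporting_read_count < params$min_column_depth) break
    el$name <- sprintf("element%d", length(elements) + 1L)
    el <- detect_structure(el)
    elements[[el$name]] <- el
    mt <- match_reads_cpp(pool$reads, el$sequence, params$recruit_word,
                          params$min_overlap_identity, params$min_overlap_bp)
    drop <- mt$matched
    drop[match(el$reads$read_id, pool$ids)] <- TRUE
    if (!any(drop)) break  # guarantee the pool shrinks
    if (all(drop)) break
    keep_sources <- !is.null(pool$sources)
    pool <- read_set(pool$reads[!drop], ids = pool$ids[!drop],
                     coverage = pool$coverage,
                     sources = if (keep_sources)
                       pool$sources[!drop, , drop = FALSE] else NULL)
  }
  if (length(elements) > 1L) {
    ord <- order(-vapply(elements, function(e) e$supporting_read_count, 1))
    elements <- elements[ord]
    for (i in seq_along(elements))
      elements[[i]]$name <- sprintf("element%d", i)
    names(elements) <- vapply(elements, function(e) e$name, "")
  }
  if (!is.null(config) && length(elements)) {
    for (i in seq_along(elements)) {
      elements[[i]]$abundance <- quantify_element(
        reads, elements[[i]]$sequence, min_identity = min_identity,
        config = config, element_name = elements[[i]]$name)
    }
    attr(elements, "abundance_report") <-
      abundance_report(lapply(elements, function(e) e$abundance))
  }
  elements
}
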