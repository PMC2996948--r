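# Synthetic genomes with planted repeat structure and complete ground
# truth, plus fixed-length WGS read pools sampled from them.  The
# simulator is substitution-only by default: every planted copy is the
# family consensus mutated independently per base, so identity bookkeeping
# is exact.

#' Describe a repeat family to plant in a synthetic genome
#'
#' @param name Family name (token).
#' @param consensus_length_bp Length of the family consensus. For
#'   `tandem`/`telomeric`/`low_complexity` families this is the unit (or
#'   tract) length.
#' @param copy_count Number of copies; for `tandem`/`telomeric` families,
#'   the total number of units across arrays.
#' @param divergence Per-base substitution probability applied
#'   independently to each copy (0 to 0.5).
#' @param ltr_length_bp Length of identical-at-birth terminal direct
#'   repeats (0 = none; `ltr_retro` only).
#' @param fragmentation_prob Probability that a copy is truncated.
#' @param nesting_prob Probability that a copy is inserted inside a
#'   previously placed copy, splitting the host.
#' @param kind One of `"ltr_retro"`, `"tandem"`, `"telomeric"`,
#'   `"low_complexity"`.
#' @param units_per_array For array kinds, mean units per array.
#' @return A `repeat_family` specification.
#' @export
repeat_family <- function(name, consensus_length_bp, copy_count,
                          divergence = 0, ltr_length_bp = 0L,
                          fragmentation_prob = 0, nesting_prob = 0,
                          kind = c("ltr_retro", "tandem", "telomeric",
                                   "low_complexity"),
                          units_per_array = 40L) {
  kind <- match.arg(kind)
  if (divergence < 0 || divergence > 0.5)
    stop("divergence must be in [0, 0.5]")
  if (copy_count < 1) stop("copy_count must be >= 1")
  if (kind == "telomeric") consensus_length_bp <- 7L
  if (ltr_length_bp >= consensus_length_bp && ltr_length_bp > 0)
    stop("ltr_length_bp must be smaller than consensus_length_bp")
  structure(list(name = name,
                 consensus_length_bp = as.integer(consensus_length_bp),
                 copy_count = as.integer(copy_count),
                 divergence = divergence,
                 ltr_length_bp = as.integer(ltr_length_bp),
                 fragmentation_prob = fragmentation_prob,
                 nesting_prob = nesting_prob,
                 kind = kind,
                 units_per_array = as.integer(units_per_array)),
            class = "repeat_family")
}

#' Describe a synthetic genome
#'
#' @param genome_length_bp Total genome length.
#' @param families List of [repeat_family()] specifications.
#' @param base_composition Background A/C/G/T probabilities (sum to 1).
#' @param gene_count Number of compact multi-exon genes; pseudogenes are
#'   added at `pseudogene_ratio` per gene.
#' @param pseudogene_ratio Pseudogene copies per gene (default 5).
#' @param seed Integer seed controlling the whole simulation.
#' @return A `genome_spec`.
#' @export
genome_spec <- function(genome_length_bp, families = list(),
                        base_composition = c(0.30, 0.20, 0.20, 0.30),
                        gene_count = 0L, pseudogene_ratio = 5L, seed = 1L) {
  if (abs(sum(base_composition) - 1) > 1e-9)
    stop("base_composition must sum to 1")
  if (length(families) && !all(vapply(families, inherits, TRUE,
                                      "repeat_family")))
    stop("families must be repeat_family objects")
  structure(list(genome_length_bp = as.numeric(genome_length_bp),
                 families = families,
                 base_composition = as.numeric(base_composition),
                 gene_count = as.integer(gene_count),
                 pseudogene_ratio = as.integer(pseudogene_ratio),
                 seed = as.integer(seed)),
            class = "genome_spec")
}

# one ledger row for an emission, with coordinates relative to its sequence
.sub_row <- function(rel_start, rel_end, family, copy_id, identity,
                     truncated, nested_in, kind, units) {
  data.frame(rel_start = rel_start, rel_end = rel_end, family = family,
             copy_id = copy_id, identity = identity, truncated = truncated,
             nested_in = nested_in, kind = kind, units = units,
             stringsAsFactors = FALSE)
}

# draw family consensi (once each)
.draw_consensi <- function(families, comp) {
  consensi <- character(0)
  for (fam in families) {
    consensi[fam$name] <- switch(fam$kind,
      ltr_retro = {
        if (fam$ltr_length_bp > 0) {
          ltr <- random_dna(fam$ltr_length_bp, comp)
          inner <- random_dna(fam$consensus_length_bp - 2 * fam$ltr_length_bp,
                              comp)
          paste0(ltr, inner, ltr)
        } else random_dna(fam$consensus_length_bp, comp)
      },
      tandem = random_dna(fam$consensus_length_bp, comp),
      telomeric = "TTTAGGG",
      low_complexity = {
        unit <- sample(c("A", "T", "AT", "GA", "CT"), 1L)
        substr(strrep(unit, ceiling(fam$consensus_length_bp / nchar(unit))),
               1L, fam$consensus_length_bp)
      })
  }
  consensi
}

#' Simulate a genome with planted repeats and complete ground truth
#'
#' The background is drawn i.i.d. from the spec's base composition; each
#' family consensus is drawn once and every copy is the consensus mutated
#' at the family divergence, optionally truncated or nested inside a
#' previously generated copy (the host is split and recorded as two
#' placement fragments sharing one `copy_id`).  LTR families carry
#' identical-at-birth terminal repeats that then diverge independently
#' copy by copy.  The same spec (and seed) always reproduces the same
#' genome, ledger and reads.
#'
#' @param spec A [genome_spec()].
#' @return A `genome_truth` object: `sequences` (named character),
#'   `placements` (0-based half-open ledger with family, identity,
#'   truncation and nesting attributes), `consensi` (named character),
#'   `genes` (annotation data.frame or NULL), and the `spec`.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(derive_seed(spec$seed, "genome"))
  comp <- spec$base_composition
  G <- spec$genome_length_bp
  consensi <- .draw_consensi(spec$families, comp)

  # ---- phase 1: generate copies as "emissions" (seq + relative ledger) ----
  emis <- list()   # each: seq, rows, kind, nested (flag), gene (exon info)
  for (fam in spec$families) {
    cons <- consensi[[fam$name]]
    if (fam$kind %in% c("tandem", "telomeric")) {
      units_left <- fam$copy_count
      a <- 0L
      while (units_left > 0L) {
        a <- a + 1L
        k <- min(units_left, max(2L, stats::rpois(1L, fam$units_per_array)))
        units_left <- units_left - k
        arr <- character(k)
        nsub <- 0L
        for (i in seq_len(k)) {
          m <- mutate_seq_cpp(cons, fam$divergence)
          arr[i] <- m$seq
          nsub <- nsub + m$n_sub
        }
        sq <- paste(arr, collapse = "")
        emis[[length(emis) + 1L]] <- list(
          seq = sq, kind = fam$kind, nested = FALSE,
          rows = .sub_row(0L, nchar(sq), fam$name,
                          sprintf("%s_arr%03d", fam$name, a),
                          1 - nsub / nchar(sq), FALSE, NA_character_,
                          fam$kind, k))
      }
    } else {
      nest <- stats::runif(fam$copy_count) < fam$nesting_prob
      frag <- stats::runif(fam$copy_count) < fam$fragmentation_prob
      for (i in seq_len(fam$copy_count)) {
        src <- cons
        truncated <- FALSE
        if (frag[i] && fam$kind == "ltr_retro") {
          keep <- max(50L, round(nchar(cons) * stats::runif(1L, 0.3, 0.9)))
          src <- if (stats::runif(1L) < 0.5) substr(cons, 1L, keep)
                 else substr(cons, nchar(cons) - keep + 1L, nchar(cons))
          truncated <- TRUE
        }
        m <- mutate_seq_cpp(src, fam$divergence)
        emis[[length(emis) + 1L]] <- list(
          seq = m$seq, kind = fam$kind,
          nested = nest[i] && fam$kind == "ltr_retro",
          rows = .sub_row(0L, nchar(m$seq), fam$name,
                          sprintf("%s_c%04d", fam$name, i),
                          1 - m$n_sub / nchar(m$seq), truncated,
                          NA_character_, fam$kind, NA_integer_))
      }
    }
  }

  # genes + pseudogenes (annotation material; sequence content is neutral)
  if (spec$gene_count > 0L) {
    for (g in seq_len(spec$gene_count)) {
      n_ex <- sample(2:4, 1L)
      ex_len <- pmax(60L, round(stats::rnorm(n_ex, 219, 40)))
      in_len <- pmax(60L, round(stats::rnorm(max(n_ex - 1L, 1L), 350, 100)))
      pieces <- character(0)
      exon_off <- integer(0)
      off <- 0L
      for (e in seq_len(n_ex)) {
        exon_off <- c(exon_off, off)
        pieces <- c(pieces, random_dna(ex_len[e], comp))
        off <- off + ex_len[e]
        if (e < n_ex) {
          pieces <- c(pieces, random_dna(in_len[e], comp))
          off <- off + in_len[e]
        }
      }
      sq <- paste(pieces, collapse = "")
      emis[[length(emis) + 1L]] <- list(
        seq = sq, kind = "gene", nested = FALSE,
        rows = .sub_row(0L, nchar(sq), "gene", sprintf("gene%03d", g), 1,
                        FALSE, NA_character_, "gene", NA_integer_),
        exon_off = exon_off, exon_len = ex_len)
      exonic <- paste(vapply(seq_len(n_ex), function(e) {
        substr(sq, exon_off[e] + 1L, exon_off[e] + ex_len[e])
      }, character(1)), collapse = "")
      for (p in seq_len(spec$pseudogene_ratio)) {
        m <- mutate_seq_cpp(exonic, 0.10)
        emis[[length(emis) + 1L]] <- list(
          seq = m$seq, kind = "pseudogene", nested = FALSE,
          rows = .sub_row(0L, nchar(m$seq), "pseudogene",
                          sprintf("pseudo%03d_%d", g, p),
                          1 - m$n_sub / nchar(m$seq), FALSE, NA_character_,
                          "pseudogene", NA_integer_))
      }
    }
  }

  # ---- phase 2: nesting — splice nested copies into eligible hosts ----
  consumed <- logical(length(emis))
  is_host <- vapply(emis, function(e) {
    e$kind == "ltr_retro" && !e$nested && nchar(e$seq) >= 400L &&
      nrow(e$rows) == 1L
  }, TRUE)
  for (i in seq_along(emis)) {
    if (!emis[[i]]$nested || consumed[i]) next
    hosts <- which(is_host & !consumed)
    hosts <- setdiff(hosts, i)
    if (!length(hosts)) next
    h <- if (length(hosts) == 1L) hosts else sample(hosts, 1L)
    host <- emis[[h]]
    ins <- emis[[i]]
    cut <- sample(seq(150L, nchar(host$seq) - 150L), 1L)
    ilen <- nchar(ins$seq)
    hrow <- host$rows
    rows <- rbind(
      .sub_row(0L, cut, hrow$family, hrow$copy_id, hrow$identity, TRUE,
               NA_character_, hrow$kind, NA_integer_),
      transform(ins$rows, rel_start = rel_start + cut,
                rel_end = rel_end + cut, nested_in = hrow$copy_id),
      .sub_row(cut + ilen, nchar(host$seq) + ilen, hrow$family,
               hrow$copy_id, hrow$identity, TRUE, NA_character_,
               hrow$kind, NA_integer_))
    emis[[h]] <- list(
      seq = paste0(substr(host$seq, 1L, cut), ins$seq,
                   substr(host$seq, cut + 1L, nchar(host$seq))),
      kind = "ltr_retro", nested = FALSE, rows = rows)
    is_host[h] <- FALSE
    consumed[i] <- TRUE
  }
  emis <- emis[!consumed]

  # ---- phase 3: layout with uniformly partitioned background gaps ----
  rep_bp <- sum(vapply(emis, function(e) nchar(e$seq), 1))
  if (rep_bp > G)
    stop("placements exceed genome length (", rep_bp, " > ", G, " bp)")
  bg_bp <- G - rep_bp
  emis <- emis[sample(length(emis))]
  n_gap <- length(emis) + 1L
  gaps <- if (n_gap == 1L) bg_bp else {
    cuts <- sort(stats::runif(n_gap - 1L))
    g <- floor(diff(c(0, cuts, 1)) * bg_bp)
    g[n_gap] <- g[n_gap] + (bg_bp - sum(g))
    g
  }

  pieces <- character(2L * length(emis) + 1L)
  led <- vector("list", length(emis))
  gene_rows <- list()
  pos <- 0
  k <- 1L
  for (i in seq_along(emis)) {
    pieces[k] <- random_dna(gaps[i], comp); k <- k + 1L
    pos <- pos + gaps[i]
    e <- emis[[i]]
    len <- nchar(e$seq)
    minus <- e$kind %in% c("ltr_retro", "pseudogene") &&
      stats::runif(1L) < 0.5
    sq <- if (minus) revcomp(e$seq) else e$seq
    pieces[k] <- sq; k <- k + 1L
    rows <- e$rows
    if (minus) {
      new_start <- len - rows$rel_end
      rows$rel_end <- len - rows$rel_start
      rows$rel_start <- new_start
    }
    led[[i]] <- data.frame(
      contig_id = "g1",
      start = pos + rows$rel_start, end = pos + rows$rel_end,
      strand = if (minus) "-" else "+",
      family = rows$family, copy_id = rows$copy_id,
      identity = rows$identity, truncated = rows$truncated,
      nested_in = rows$nested_in, kind = rows$kind, units = rows$units,
      stringsAsFactors = FALSE)
    if (e$kind == "gene") {
      gid <- e$rows$copy_id[1L]
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        contig_id = "g1", source = "repeatscape", type = "gene",
        start = pos, end = pos + len, score = NA_real_, strand = "+",
        phase = NA_character_, ID = gid, stringsAsFactors = FALSE)
      for (x in seq_along(e$exon_off)) {
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          contig_id = "g1", source = "repeatscape", type = "exon",
          start = pos + e$exon_off[x], end = pos + e$exon_off[x] + e$exon_len[x],
          score = NA_real_, strand = "+", phase = NA_character_,
          ID = paste0(gid, ".e", x), stringsAsFactors = FALSE)
      }
    }
    pos <- pos + len
  }
  pieces[k] <- random_dna(gaps[n_gap], comp)
  genome <- paste(pieces, collapse = "")
  stopifnot(nchar(genome) == G)

  placements <- do.call(rbind, led)
  if (is.null(placements))
    placements <- data.frame(contig_id = character(0), start = integer(0),
                             end = integer(0), strand = character(0),
                             family = character(0), copy_id = character(0),
                             identity = numeric(0), truncated = logical(0),
                             nested_in = character(0), kind = character(0),
                             units = integer(0), stringsAsFactors = FALSE)
  placements <- placements[order(placements$start), , drop = FALSE]
  rownames(placements) <- NULL
  stopifnot(all(placements$start >= 0), all(placements$end <= G))
  genes_df <- if (length(gene_rows)) do.call(rbind, gene_rows) else NULL

  structure(list(sequences = c(g1 = genome),
                 placements = placements,
                 consensi = consensi,
                 genes = genes_df,
                 spec = spec),
            class = "genome_truth")
}

#' @export
print.genome_truth <- function(x, ...) {
  G <- sum(nchar(x$sequences))
  rep_rows <- x$placements[!x$placements$kind %in% c("gene", "pseudogene"), ]
  cat(sprintf("Synthetic genome: %.3g bp, %d placements, %d repeat families\n",
              G, nrow(x$placements), length(x$consensi)))
  cat(sprintf("  planted repeat fraction: %.1f%%\n",
              100 * sum(rep_rows$end - rep_rows$start) / G))
  invisible(x)
}

#' Per-family planted genome fractions and copy counts
#'
#' The scoring key for abundance-recovery tests: fraction is total planted
#' bp over genome bp; counts include truncated copies (array families
#' count units).
#'
#' @param truth A `genome_truth`.
#' @return data.frame with `family`, `bp`, `fraction`, `copies`.
#' @export
truth_fractions <- function(truth) {
  stopifnot(inherits(truth, "genome_truth"))
  G <- sum(nchar(truth$sequences))
  pl <- truth$placements
  fams <- names(truth$consensi)
  if (!length(fams))
    return(data.frame(family = character(0), bp = numeric(0),
                      fraction = numeric(0), copies = integer(0),
                      stringsAsFactors = FALSE))
  out <- lapply(fams, function(f) {
    rows <- pl[pl$family == f, , drop = FALSE]
    bp <- sum(rows$end - rows$start)
    copies <- if (all(is.na(rows$units))) {
      length(unique(rows$copy_id))
    } else {
      sum(rows$units, na.rm = TRUE)
    }
    data.frame(family = f, bp = bp, fraction = bp / G,
               copies = as.integer(copies), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a fixed-length WGS read pool from a genome
#'
#' Read count is `round(coverage * genome_length / read_length)`; start
#' positions and strands are uniform; substitution errors are applied at
#' `error_rate`.  The returned pool records its true source loci for
#' scoring.
#'
#' @param truth A `genome_truth` (or a single DNA string).
#' @param read_length_bp Read length (e.g. 40, 42 or 60).
#' @param coverage Genome-equivalent coverage of the pool (e.g. 0.036).
#' @param error_rate Per-base substitution error probability (<= 0.1).
#' @param seed Integer seed.
#' @return A [read_set()] with `sources` (`start` 0-based, `strand`,
#'   `n_errors`) and recomputed `coverage`.
#' @export
simulate_reads <- function(truth, read_length_bp = 60L, coverage = 0.036,
                           error_rate = 0, seed = 1L) {
  genome <- if (inherits(truth, "genome_truth")) truth$sequences[[1L]]
            else as_contig(truth)
  if (coverage <= 0) stop("coverage must be positive")
  if (error_rate < 0 || error_rate > 0.1)
    stop("error_rate must be in [0, 0.1]")
  G <- nchar(genome)
  L <- as.integer(read_length_bp)
  if (L > G) stop("read length exceeds genome length")
  N <- round(coverage * G / L)
  set.seed(derive_seed(seed, "reads"))
  starts <- sample.int(G - L + 1L, N, replace = TRUE)
  minus <- stats::runif(N) < 0.5
  ex <- extract_reads_cpp(genome, starts, L, minus, error_rate)
  read_set(ex$reads,
           ids = sprintf("r%07d", seq_len(N)),
           coverage = as.numeric(N) * L / G,
           sources = data.frame(start = starts - 1L,
                                strand = ifelse(minus, "-", "+"),
                                n_errors = ex$n_errors))
}

#' Bundled desk-scale pine-like genome specification
#'
#' A 10 Mb genome emulating the repeat landscape of a large conifer
#' genome: a young ~4.2 kb LTR family at ~1.6% of the genome with low
#' divergence, a ~4 kb family at ~1.3%, a 50 bp tandem ("centromeric")
#' family at ~0.27%, telomeric TTTAGGG arrays at ~0.24%, several ancient
#' highly diverged families jointly occupying over half the genome,
#' low-complexity tracts, and compact genes with five pseudogene copies
#' per gene.
#'
#' @param seed Integer seed.
#' @param genome_length_bp Genome size (default 1e7).
#' @return A [genome_spec()].
#' @export
default_pine_spec <- function(seed = 1L, genome_length_bp = 1e7) {
  G <- genome_length_bp
  fams <- list(
    repeat_family("youngLTR", 4200L, copy_count = max(1L, round(0.016 * G / 4200)),
                  divergence = 0.03, ltr_length_bp = 300L,
                  fragmentation_prob = 0.10, nesting_prob = 0.05),
    repeat_family("agedLTR", 4000L, copy_count = max(1L, round(0.013 * G / 4000)),
                  divergence = 0.05, ltr_length_bp = 300L,
                  fragmentation_prob = 0.20, nesting_prob = 0.05),
    repeat_family("cen_rpt", 50L, copy_count = max(1L, round(0.0027 * G / 50)),
                  divergence = 0.02, kind = "tandem", units_per_array = 40L),
    repeat_family("tel_rpt", 7L, copy_count = max(1L, round(0.0024 * G / 7)),
                  divergence = 0, kind = "telomeric", units_per_array = 120L),
    repeat_family("ancient1", 3000L, copy_count = max(1L, round(0.11 * G / 3000)),
                  divergence = 0.20, fragmentation_prob = 0.3,
                  nesting_prob = 0.10),
    repeat_family("ancient2", 3500L, copy_count = max(1L, round(0.11 * G / 3500)),
                  divergence = 0.22, fragmentation_prob = 0.3,
                  nesting_prob = 0.10),
    repeat_family("ancient3", 4500L, copy_count = max(1L, round(0.11 * G / 4500)),
                  divergence = 0.25, fragmentation_prob = 0.3,
                  nesting_prob = 0.10),
    repeat_family("ancient4", 5000L, copy_count = max(1L, round(0.11 * G / 5000)),
                  divergence = 0.28, fragmentation_prob = 0.3,
                  nesting_prob = 0.10),
    repeat_family("ancient5", 6000L, copy_count = max(1L, round(0.11 * G / 6000)),
                  divergence = 0.30, fragmentation_prob = 0.3,
                  nesting_prob = 0.10),
    repeat_family("lowcomp", 200L, copy_count = max(3L, round(G / 4e5)),
                  divergence = 0, kind = "low_complexity"))
  genome_spec(genome_length_bp = G, families = fams,
              base_composition = c(0.301, 0.204, 0.201, 0.294),
              gene_count = 4L, pseudogene_ratio = 5L, seed = seed)
}
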