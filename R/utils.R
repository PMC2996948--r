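# Internal helpers shared across modules.

# Deterministic sub-seed derivation: one user-facing seed per run, one
# derived stream per module/stage.  Kept below 2^31 - 1.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

# Reverse complement of character vector(s) of DNA.
revcomp <- function(x) {
  as.character(revcomp_cpp(as.character(x)))
}

# Random DNA string of length n with given ACGT composition (uses R's RNG).
random_dna <- function(n, composition = rep(0.25, 4)) {
  stopifnot(n >= 0)
  if (n == 0) return("")
  random_dna_cpp(as.integer(n), as.numeric(composition))
}

# Base frequencies (A, C, G, T) over non-N characters of a string vector.
base_frequencies <- function(x) {
  x <- paste(x, collapse = "")
  counts <- vapply(c("A", "C", "G", "T"), function(b) {
    lengths(regmatches(x, gregexpr(b, x, fixed = TRUE)))
  }, numeric(1))
  tot <- sum(counts)
  if (tot == 0) stop("sequence contains no A/C/G/T bases")
  counts / tot
}

is_dna_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)
}

# Coerce a contig argument (plain string, or a row of read_fasta() output)
# to a single uppercase DNA string.
as_contig <- function(contig) {
  if (is.data.frame(contig)) {
    stopifnot(nrow(contig) == 1L, "sequence" %in% names(contig))
    contig <- contig$sequence
  }
  if (!is_dna_string(contig)) stop("contig must be a single non-empty DNA string")
  toupper(contig)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
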