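#' Analysis configuration
#'
#' Bundles the run-level constants shared by the estimators: the assumed
#' genome size, the chromosome count used for per-chromosome averages, the
#' pair of identity stringencies used for coverage profiling, the RNG seed,
#' and the display window for coverage histograms.
#'
#' The defaults describe a loblolly-pine-scale target: a 22 Gb genome with
#' 12 chromosomes, profiled at 75% and 99% nucleotide identity, with
#' coverage histograms averaged in 50 bp windows.
#'
#' @param genome_size_bp Assumed genome size in base pairs (> 0).
#' @param n_chromosomes Haploid chromosome count (> 0).
#' @param identity_thresholds Strictly increasing pair of identity
#'   fractions in (0, 1]; the lax and strict stringencies for coverage
#'   profiling.
#' @param rng_seed Integer seed; all module-level random streams are
#'   derived deterministically from it.
#' @param window_bp Window size (bp, >= 1) for display histograms of
#'   coverage maps.
#' @return An object of class `analysis_config`.
#' @examples
#' cfg <- analysis_config()
#' cfg$genome_size_bp
#' @export
analysis_config <- function(genome_size_bp = 2.2e10, n_chromosomes = 12L,
                            identity_thresholds = c(0.75, 0.99),
                            rng_seed = 1L, window_bp = 50L) {
  if (!is.numeric(genome_size_bp) || length(genome_size_bp) != 1L ||
      genome_size_bp <= 0)
    stop("genome_size_bp must be a positive number")
  if (!is.numeric(n_chromosomes) || length(n_chromosomes) != 1L ||
      n_chromosomes < 1)
    stop("n_chromosomes must be a positive integer")
  if (length(identity_thresholds) != 2L ||
      any(identity_thresholds <= 0) || any(identity_thresholds > 1))
    stop("identity_thresholds must be two fractions in (0, 1]")
  if (diff(identity_thresholds) <= 0)
    stop("identity_thresholds must be strictly increasing")
  if (!is.numeric(window_bp) || window_bp < 1)
    stop("window_bp must be >= 1")
  structure(
    list(genome_size_bp = as.numeric(genome_size_bp),
         n_chromosomes = as.integer(n_chromosomes),
         identity_thresholds = as.numeric(identity_thresholds),
         rng_seed = as.integer(rng_seed),
         window_bp = as.integer(window_bp)),
    class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat(sprintf("  genome size:         %.3g bp\n", x$genome_size_bp))
  cat(sprintf("  chromosomes:         %d\n", x$n_chromosomes))
  cat(sprintf("  identity thresholds: %.2f / %.2f\n",
              x$identity_thresholds[1], x$identity_thresholds[2]))
  cat(sprintf("  rng seed:            %d\n", x$rng_seed))
  cat(sprintf("  display window:      %d bp\n", x$window_bp))
  invisible(x)
}
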