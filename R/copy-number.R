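#' Copy number from ddPCR amplicon concentrations
#'
#' `CN = T / ((R1 + R2) / 2) * N_R`, where `T` is the target amplicon
#' concentration, `R1` and `R2` the concentrations of two reference
#' amplicons, and `N_R` the genomic copy number of the reference loci
#' (2 for diploid references).  When concentration confidence intervals
#' are supplied, the CN interval is propagated conservatively as the
#' range of the ratio over the CI box:
#' `[T_lo / mean(R_hi), T_hi / mean(R_lo)] * N_R`.
#'
#' @param target Target concentration (copies/ul).
#' @param ref1,ref2 Reference concentrations.
#' @param n_ref Reference copy number (default 2).
#' @param target_ci,ref1_ci,ref2_ci Optional length-2 `c(lo, hi)`
#'   concentration CIs.
#' @return List with `cn` and (when CIs are supplied) `ci`.
#' @export
ddpcr_cn <- function(target, ref1, ref2, n_ref = 2,
                     target_ci = NULL, ref1_ci = NULL, ref2_ci = NULL) {
  if (any(c(target, ref1, ref2) < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (n_ref < 1) stop("`n_ref` must be >= 1", call. = FALSE)
  if (ref1 + ref2 == 0) {
    stop("both reference concentrations are zero; CN undefined",
         call. = FALSE)
  }
  cn <- target / ((ref1 + ref2) / 2) * n_ref
  out <- list(cn = cn)
  if (!is.null(target_ci) && !is.null(ref1_ci) && !is.null(ref2_ci)) {
    ref_hi <- (ref1_ci[2] + ref2_ci[2]) / 2
    ref_lo <- (ref1_ci[1] + ref2_ci[1]) / 2
    lo <- if (ref_hi > 0) target_ci[1] / ref_hi * n_ref else 0
    hi <- if (ref_lo > 0) target_ci[2] / ref_lo * n_ref else Inf
    out$ci <- c(lo, hi)
  }
  out
}

#' Copy number from a simulated ddPCR readout
#'
#' @param readout Data.frame from [simulate_ddpcr()].
#' @param n_ref Reference copy number (default 2).
#' @return List with `cn` and `ci`.
#' @export
ddpcr_cn_from_readout <- function(readout, n_ref = 2) {
  g <- function(ch, col) readout[readout$channel == ch, col]
  ddpcr_cn(g("T", "conc"), g("R1", "conc"), g("R2", "conc"), n_ref,
           target_ci = c(g("T", "conc_lo"), g("T", "conc_hi")),
           ref1_ci = c(g("R1", "conc_lo"), g("R1", "conc_hi")),
           ref2_ci = c(g("R2", "conc_lo"), g("R2", "conc_hi")))
}

#' Convert kmer coverage to per-base coverage
#'
#' A read of length `R` contains `R - K + 1` kmers of size `K`, so the
#' per-base coverage is `C = C_K * R / (R - K + 1)`.
#'
#' @param c_k Kmer coverage (fold).
#' @param read_length Average read length `R` in bp.
#' @param k Kmer size in bp (`1 <= k <= read_length`).
#' @return Per-base coverage (fold).
#' @export
kmer_to_base_coverage <- function(c_k, read_length, k) {
  if (any(c_k < 0)) stop("`c_k` must be non-negative", call. = FALSE)
  if (k < 1 || k > read_length) {
    stop("`k` must satisfy 1 <= k <= read_length", call. = FALSE)
  }
  c_k * read_length / (read_length - k + 1)
}

#' Naive coverage from sequencing effort and genome size
#'
#' Total sequenced bases divided by the 1C genome size (from flow
#' cytometry), assuming a diploid genome.
#'
#' @param total_bp Total bases in the library.
#' @param genome_size_1c_bp 1C genome size in bp.
#' @return Fold coverage.
#' @export
naive_coverage <- function(total_bp, genome_size_1c_bp) {
  stop_if_not_scalar_pos(genome_size_1c_bp, "genome_size_1c_bp")
  if (any(total_bp <= 0)) stop("`total_bp` must be positive",
                               call. = FALSE)
  total_bp / genome_size_1c_bp
}
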