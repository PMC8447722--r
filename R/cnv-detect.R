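#' Detector parameters for window-merging CNV calling
#'
#' @param sd_threshold Cross-library coverage SD above which a window
#'   seeds a CNV (default 0.7, separating the diploid lowSD background
#'   from variable windows).
#' @param alpha Significance level for the between-window coverage
#'   correlation tests (default 0.05).
#' @param min_windows Minimum run length, in windows, for a reported CNV
#'   (default 3; applied after breakpoint bridging).
#' @param bridge_gap Maximum gap, in windows, bridged between two CNV
#'   runs when the flanking windows correlate (default 1, a single
#'   breakpoint window).
#' @param correlation `"partial"` (Pearson with prep batch partialled
#'   out, the default when library metadata is supplied) or
#'   `"pearson"`.
#' @param p_adjust Optional multiple-testing correction for the
#'   adjacency tests (`"none"`, the default, or `"BH"`).
#' @return A `detector_params` list.
#' @export
detector_params <- function(sd_threshold = 0.7, alpha = 0.05,
                            min_windows = 3, bridge_gap = 1,
                            correlation = c("partial", "pearson"),
                            p_adjust = c("none", "BH")) {
  stop_if_not_scalar_pos(sd_threshold, "sd_threshold")
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0, 1)",
                                      call. = FALSE)
  if (min_windows < 1) stop("`min_windows` must be >= 1", call. = FALSE)
  structure(list(sd_threshold = sd_threshold, alpha = alpha,
                 min_windows = as.integer(min_windows),
                 bridge_gap = as.integer(bridge_gap),
                 correlation = match.arg(correlation),
                 p_adjust = match.arg(p_adjust)),
            class = "detector_params")
}

# p-values of the (partial) Pearson correlation between pairs of rows of
# the residualized matrix E; `i` and `j` are row indices of the pairs.
pair_cor_p <- function(E, i, j, df) {
  a <- E[i, , drop = FALSE]
  b <- E[j, , drop = FALSE]
  sa <- sqrt(rowSums(a^2))
  sb <- sqrt(rowSums(b^2))
  r <- rowSums(a * b) / (sa * sb)
  r[sa == 0 | sb == 0] <- NA_real_
  r <- pmax(pmin(r, 1), -1)
  tval <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  tval[abs(r) == 1] <- sign(r[abs(r) == 1]) * Inf
  2 * stats::pt(-abs(tval), df = df)
}

#' Detect copy-number-variable regions by merging adjacent windows
#'
#' Implements the window-merging CNV caller: per contig, (1) a window
#' seeds a CNV if its cross-library coverage SD exceeds
#' `sd_threshold`; (2) two adjacent seed windows belong to the same CNV
#' if their per-library coverage vectors are significantly correlated
#' at `alpha` (partial correlation controlling for prep batch by
#' default); (3) the very first and last window of a contig, which
#' often show deviant coverage, are merged into a neighboring CNV;
#' (4) two CNVs separated by exactly one breakpoint window are merged
#' when the two windows flanking the gap correlate significantly,
#' iterated to a fixpoint; (5) finally only runs of at least
#' `min_windows` adjacent windows are reported.
#'
#' Detection is fully deterministic: the same matrix always yields the
#' same CNV list.
#'
#' @param matrix A normalized `cov_matrix` at CNV resolution
#'   (typically 5-kb windows).
#' @param params A [detector_params()].
#' @param library_meta Optional library metadata with a `prep_batch`
#'   column, required for the default partial correlation.
#' @return A `cnv_regions` data.frame (`cnv_id`, `contig`, `start`,
#'   `end`, `n_windows`, `mean_sd`, `placement`) with the per-library
#'   mean normalized coverage of each region in attribute
#'   `lib_coverage` and the window index range in columns `first_win`,
#'   `last_win` (global window indices).
#' @export
detect_cnvs <- function(matrix, params = detector_params(),
                        library_meta = NULL) {
  stopifnot(inherits(matrix, "cov_matrix"),
            inherits(params, "detector_params"))
  if (!matrix$normalized) {
    stop("CNV detection requires an exon-normalized coverage matrix",
         call. = FALSE)
  }
  n_lib <- ncol(matrix$values)
  sds <- window_sd(matrix)

  Z <- NULL
  if (params$correlation == "partial") {
    if (is.null(library_meta)) {
      Z <- NULL  # falls back to plain Pearson residuals (mean-centering)
    } else {
      meta <- library_meta[match(matrix$library_ids,
                                 library_meta$library_id), ]
      if (anyNA(meta$library_id)) {
        stop("library metadata missing for some libraries", call. = FALSE)
      }
      Z <- meta[, "prep_batch", drop = FALSE]
    }
  }
  proj <- residual_projector(Z, n_lib)
  df <- n_lib - 2L - proj$q
  if (df < 1L) stop("too few libraries for the correlation test",
                    call. = FALSE)
  E <- matrix$values %*% proj$M  # residualized (and centered) rows

  ws <- matrix$windows
  seed <- sds > params$sd_threshold

  regions <- list()
  for (ctg in unique(ws$contig)) {
    idx <- ws$index[ws$contig == ctg]
    W <- length(idx)
    if (W < params$min_windows) {
      warning("contig ", ctg, " has fewer than min_windows windows; skipped")
      next
    }
    runs <- contig_runs(E, idx, seed[idx], df, params)
    for (r in runs) {
      gi <- idx[r[1]:r[2]]
      regions[[length(regions) + 1L]] <- list(
        contig = ctg,
        start = ws$start[gi[1]],
        end = ws$end[gi[length(gi)]],
        first_win = gi[1], last_win = gi[length(gi)],
        n_windows = length(gi),
        mean_sd = mean(sds[gi]),
        lib_cov = colMeans(matrix$values[gi, , drop = FALSE]),
        whole = length(gi) == W,
        edge = r[1] == 1L || r[2] == W)
    }
  }

  if (length(regions) == 0) {
    out <- data.frame(cnv_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      first_win = integer(0), last_win = integer(0),
                      n_windows = integer(0), mean_sd = numeric(0),
                      placement = character(0), stringsAsFactors = FALSE)
    attr(out, "lib_coverage") <-
      matrix(numeric(0), 0, n_lib, dimnames = list(NULL, matrix$library_ids))
    class(out) <- c("cnv_regions", "data.frame")
    return(out)
  }

  out <- data.frame(
    cnv_id = sprintf("CNV%04d", seq_along(regions)),
    contig = vapply(regions, `[[`, character(1), "contig"),
    start = vapply(regions, `[[`, numeric(1), "start"),
    end = vapply(regions, `[[`, numeric(1), "end"),
    first_win = vapply(regions, `[[`, numeric(1), "first_win"),
    last_win = vapply(regions, `[[`, numeric(1), "last_win"),
    n_windows = vapply(regions, `[[`, numeric(1), "n_windows"),
    mean_sd = vapply(regions, `[[`, numeric(1), "mean_sd"),
    placement = vapply(regions, function(r) {
      if (r$whole) "whole-contig" else if (r$edge) "contig-edge"
      else "internal"
    }, character(1)),
    stringsAsFactors = FALSE)
  lib_cov <- do.call(rbind, lapply(regions, `[[`, "lib_cov"))
  rownames(lib_cov) <- out$cnv_id
  attr(out, "lib_coverage") <- lib_cov
  class(out) <- c("cnv_regions", "data.frame")
  out
}

# Merge-rule engine for one contig.  `idx` are global window indices,
# `seed` the per-window SD flags restricted to this contig.  Returns a
# list of c(first, last) positions (1-based within the contig).
contig_runs <- function(E, idx, seed, df, params) {
  W <- length(seed)
  # (1)+(2): adjacent seed windows with significant coverage correlation
  if (W > 1L) {
    p_adj <- pair_cor_p(E, idx[-W], idx[-1], df)
    if (params$p_adjust == "BH") p_adj <- stats::p.adjust(p_adj, "BH")
    link <- seed[-W] & seed[-1] & !is.na(p_adj) & p_adj < params$alpha
  } else {
    link <- logical(0)
  }
  runs <- list()
  i <- 1L
  while (i <= W) {
    if (!seed[i]) { i <- i + 1L; next }
    j <- i
    while (j < W && link[j]) j <- j + 1L
    runs[[length(runs) + 1L]] <- c(i, j)
    i <- j + 1L
  }

  # (3) contig-edge windows, whose coverage is often deviant, join a
  # neighboring CNV run unconditionally; a singleton edge run is
  # absorbed rather than left adjacent
  if (length(runs) > 0) {
    k <- which(vapply(runs, `[[`, numeric(1), 1) == 2L)
    if (length(k) == 1L) {
      if (identical(runs[[1]], c(1L, 1L)) ||
          identical(runs[[1]], c(1, 1))) runs[[1]] <- NULL
      k <- which(vapply(runs, `[[`, numeric(1), 1) == 2L)
      runs[[k]][1] <- 1L
    }
    nr <- length(runs)
    k <- which(vapply(runs, `[[`, numeric(1), 2) == W - 1L)
    if (length(k) == 1L) {
      if (identical(runs[[nr]], c(W, W)) ||
          identical(runs[[nr]], c(as.integer(W), as.integer(W)))) {
        runs[[nr]] <- NULL
      }
      k <- which(vapply(runs, `[[`, numeric(1), 2) == W - 1L)
      runs[[k]][2] <- W
    }
  }

  # (4) bridge single-window breakpoints while flanking windows correlate
  repeat {
    merged <- FALSE
    if (length(runs) > 1) {
      for (k in seq_len(length(runs) - 1L)) {
        gap <- runs[[k + 1L]][1] - runs[[k]][2] - 1L
        if (gap >= 1L && gap <= params$bridge_gap) {
          p <- pair_cor_p(E, idx[runs[[k]][2]], idx[runs[[k + 1L]][1]], df)
          if (!is.na(p) && p < params$alpha) {
            runs[[k]] <- c(runs[[k]][1], runs[[k + 1L]][2])
            runs[[k + 1L]] <- NULL
            merged <- TRUE
            break
          }
        }
      }
    }
    if (!merged) break
  }

  # (5) minimum-length filter
  Filter(function(r) r[2] - r[1] + 1L >= params$min_windows, runs)
}

#' Classify contigs as B-contigs
#'
#' A contig nearly all of whose length lies inside CNV regions behaves
#' like a B-chromosome fragment: present in variable copy number as a
#' unit.  The CNV-covered fraction of each contig is compared against
#' the 90% and 95% thresholds.
#'
#' @param cnvs A `cnv_regions` data.frame.
#' @param window_set The `window_set` the CNVs were called on.
#' @param fraction Additional threshold reported as `is_b` (default
#'   0.90).
#' @return Data.frame: `contig`, `contig_bp`, `cnv_bp`, `cnv_fraction`,
#'   `is_b`, `is_b90`, `is_b95`.
#' @export
classify_b_contigs <- function(cnvs, window_set, fraction = 0.90) {
  ctg_bp <- tapply(window_set$end - window_set$start, window_set$contig,
                   sum)
  cnv_bp <- stats::setNames(numeric(length(ctg_bp)), names(ctg_bp))
  if (nrow(cnvs) > 0) {
    per <- tapply(cnvs$end - cnvs$start, cnvs$contig, sum)
    cnv_bp[names(per)] <- per
  }
  frac <- as.numeric(cnv_bp / ctg_bp)
  data.frame(contig = names(ctg_bp), contig_bp = as.numeric(ctg_bp),
             cnv_bp = as.numeric(cnv_bp), cnv_fraction = frac,
             is_b = frac >= fraction, is_b90 = frac >= 0.90,
             is_b95 = frac >= 0.95,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summary statistics of a CNV call set
#'
#' @param cnvs A `cnv_regions` data.frame (regions must not overlap).
#' @param assembly_bp Total assembly length in bp.
#' @return List: `count`, `total_bp`, `assembly_fraction`, `n50_bp`
#'   (the length L such that CNVs of length >= L sum to at least half
#'   of the total CNV length).
#' @export
cnv_summary <- function(cnvs, assembly_bp) {
  stop_if_not_scalar_pos(assembly_bp, "assembly_bp")
  if (nrow(cnvs) == 0) {
    return(list(count = 0L, total_bp = 0, assembly_fraction = 0,
                n50_bp = 0))
  }
  len <- sort(cnvs$end - cnvs$start, decreasing = TRUE)
  total <- sum(len)
  n50 <- len[which(cumsum(len) >= total / 2)[1]]
  list(count = nrow(cnvs), total_bp = total,
       assembly_fraction = total / assembly_bp, n50_bp = n50)
}

#' Placement of a CNV on its contig
#'
#' @param cnv One row of a `cnv_regions` data.frame.
#' @param window_set The `window_set` used for detection.
#' @return `"whole-contig"` if the CNV covers every window of its
#'   contig, `"contig-edge"` if it includes the first or last window
#'   but not all, otherwise `"internal"`.
#' @export
cnv_placement <- function(cnv, window_set) {
  idx <- window_set$index[window_set$contig == cnv$contig]
  first <- cnv$first_win == idx[1]
  last <- cnv$last_win == idx[length(idx)]
  if (first && last) "whole-contig"
  else if (first || last) "contig-edge"
  else "internal"
}
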