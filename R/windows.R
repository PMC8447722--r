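#' Tile an assembly into fixed-size windows
#'
#' Cuts every contig into consecutive, non-overlapping windows of
#' `window_size` base pairs using 0-based half-open (BED) coordinates.
#' When a contig length is not a multiple of the window size the terminal
#' partial window is kept by default, so the tiling conserves total
#' assembly length.
#'
#' @param contig_lengths Named numeric vector of contig lengths in bp.
#' @param window_size Window size in bp (the analyses here use 5 kb for
#'   CNV detection and 50 kb for genome-wide overviews).
#' @param drop_partial Drop terminal windows shorter than `window_size`?
#' @return A `window_set` data.frame with columns `contig`, `start`,
#'   `end`, `index` (1-based running index over all windows).
#' @examples
#' tile_windows(c(ctgA = 12000), 5000)
#' @export
tile_windows <- function(contig_lengths, window_size, drop_partial = FALSE) {
  if (length(contig_lengths) == 0) {
    stop("`contig_lengths` must contain at least one contig", call. = FALSE)
  }
  if (is.null(names(contig_lengths)) || anyNA(names(contig_lengths)) ||
      any(names(contig_lengths) == "")) {
    stop("`contig_lengths` must be a named vector", call. = FALSE)
  }
  if (any(!is.finite(contig_lengths)) || any(contig_lengths <= 0)) {
    stop("all contig lengths must be positive", call. = FALSE)
  }
  stop_if_not_scalar_pos(window_size, "window_size")

  pieces <- lapply(names(contig_lengths), function(ctg) {
    len <- contig_lengths[[ctg]]
    starts <- seq.int(0L, len - 1L, by = window_size)
    ends <- pmin(starts + window_size, len)
    data.frame(contig = ctg, start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  ws <- do.call(rbind, pieces)
  if (drop_partial) {
    ws <- ws[ws$end - ws$start == window_size, , drop = FALSE]
  }
  ws$index <- seq_len(nrow(ws))
  rownames(ws) <- NULL
  class(ws) <- c("window_set", "data.frame")
  attr(ws, "window_size") <- window_size
  attr(ws, "contig_lengths") <- contig_lengths
  ws
}

#' Construct a window coverage matrix
#'
#' Bundles a [tile_windows()] window set with a windows-by-libraries
#' matrix of mean per-base depth of coverage.  The `normalized` flag
#' records whether [normalize_coverage()] has been applied.
#'
#' @param window_set A `window_set` from [tile_windows()].
#' @param values Numeric matrix, one row per window, one column per
#'   library; column names are the library ids.
#' @param normalized Logical flag.
#' @return A `cov_matrix` object.
#' @export
coverage_matrix <- function(window_set, values, normalized = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != nrow(window_set)) {
    stop("`values` must have one row per window", call. = FALSE)
  }
  if (is.null(colnames(values))) {
    stop("`values` must carry library ids as column names", call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("coverage values must be non-negative", call. = FALSE)
  }
  structure(list(windows = window_set, values = values,
                 library_ids = colnames(values),
                 normalized = isTRUE(normalized)),
            class = "cov_matrix")
}

#' @export
print.cov_matrix <- function(x, ...) {
  cat(sprintf("<cov_matrix> %d windows x %d libraries (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Exon-normalize a raw coverage matrix
#'
#' Divides each library's per-window mean per-base coverage by half that
#' library's mean exon coverage.  Exons behave like single-copy diploid
#' sequence, so diploid regions score 2 after normalization and window
#' values read directly as copy number.
#'
#' @param matrix A raw `cov_matrix`.
#' @param exon_mean Named numeric vector of mean exon coverage (fold) per
#'   library; every library in the matrix must be present.
#' @return A normalized `cov_matrix`.
#' @export
normalize_coverage <- function(matrix, exon_mean) {
  stopifnot(inherits(matrix, "cov_matrix"))
  if (matrix$normalized) {
    stop("matrix is already normalized", call. = FALSE)
  }
  missing <- setdiff(matrix$library_ids, names(exon_mean))
  if (length(missing) > 0) {
    stop("no exon mean coverage for library: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  em <- exon_mean[matrix$library_ids]
  if (any(!is.finite(em)) || any(em <= 0)) {
    stop("exon mean coverage must be positive for every library",
         call. = FALSE)
  }
  vals <- sweep(matrix$values, 2L, em / 2, "/")
  coverage_matrix(matrix$windows, vals, normalized = TRUE)
}

#' Cross-library coverage variability per window
#'
#' The sample standard deviation (n - 1 denominator) of normalized
#' coverage across all libraries, computed per window.  This is the
#' variability statistic that separates copy-number-stable from
#' copy-number-variable parts of the genome.
#'
#' @param matrix A normalized `cov_matrix` with at least two libraries.
#' @return Numeric vector of per-window standard deviations.
#' @export
window_sd <- function(matrix) {
  stopifnot(inherits(matrix, "cov_matrix"))
  if (!matrix$normalized) {
    stop("coverage matrix must be normalized before computing window SD",
         call. = FALSE)
  }
  n <- ncol(matrix$values)
  if (n < 2L) {
    stop("window SD requires at least two libraries", call. = FALSE)
  }
  mu <- rowMeans(matrix$values)
  sqrt(rowSums((matrix$values - mu)^2) / (n - 1L))
}

#' Classify windows by coverage variability
#'
#' Windows fall into three classes by their cross-library coverage SD:
#' `lowSD` (sd <= `low_hi`, copy-number-stable diploid background, the
#' bulk of the genome with a variability peak near 0.15), `interSD`
#' (`low_hi` < sd <= `inter_hi`) and `highSD` (sd > `inter_hi`).
#' Boundary values are assigned to the lower class.
#'
#' @param sd_values Numeric vector of per-window SDs.
#' @param low_hi,inter_hi Class thresholds (defaults 0.7 and 2.0).
#' @return Factor with levels `lowSD`, `interSD`, `highSD`.
#' @export
classify_variability <- function(sd_values, low_hi = 0.7, inter_hi = 2.0) {
  if (!(low_hi > 0 && low_hi < inter_hi)) {
    stop("thresholds must satisfy 0 < low_hi < inter_hi", call. = FALSE)
  }
  cls <- ifelse(sd_values <= low_hi, "lowSD",
                ifelse(sd_values <= inter_hi, "interSD", "highSD"))
  factor(cls, levels = c("lowSD", "interSD", "highSD"))
}

#' Per-class correlation of mean library coverage with genome size
#'
#' For each variability class, averages the normalized coverage of its
#' windows per library and computes the partial correlation of that mean
#' coverage with the libraries' flow-cytometry 2C genome size,
#' controlling for the listed covariates (by default the library prep
#' batch, the confounder that inflates coverage of high-GC regions in
#' some preps).
#'
#' @param matrix Normalized `cov_matrix`.
#' @param classes Factor from [classify_variability()], one per window.
#' @param library_meta Data.frame with columns `library_id`,
#'   `genome_size_2c_mb` and any covariate columns.
#' @param covariates Character vector of covariate column names
#'   (default `"prep_batch"`); use `NULL` for a plain correlation.
#' @return Data.frame with one row per class: `class`, `r`, `p`, `df`,
#'   `n`, `undefined`.
#' @export
class_coverage_vs_genome_size <- function(matrix, classes, library_meta,
                                          covariates = "prep_batch") {
  stopifnot(inherits(matrix, "cov_matrix"), matrix$normalized)
  if (length(classes) != nrow(matrix$values)) {
    stop("`classes` must have one entry per window", call. = FALSE)
  }
  meta <- library_meta[match(matrix$library_ids, library_meta$library_id), ]
  if (anyNA(meta$library_id)) {
    stop("library metadata missing for some libraries", call. = FALSE)
  }
  if (nrow(meta) < 4L) {
    stop("at least 4 libraries are required", call. = FALSE)
  }
  if (length(unique(meta$genome_size_2c_mb)) < 2L) {
    stop("at least 2 distinct genome sizes are required", call. = FALSE)
  }
  Z <- if (is.null(covariates)) NULL else meta[, covariates, drop = FALSE]
  out <- lapply(levels(classes), function(cl) {
    idx <- which(classes == cl)
    if (length(idx) == 0) {
      return(data.frame(class = cl, r = NA_real_, p = NA_real_,
                        df = NA_integer_, n = 0L, undefined = TRUE))
    }
    mean_cov <- colMeans(matrix$values[idx, , drop = FALSE])
    pc <- partial_cor(mean_cov, meta$genome_size_2c_mb, Z)
    data.frame(class = cl, r = pc$r, p = pc$p, df = pc$df,
               n = nrow(meta), undefined = pc$undefined)
  })
  do.call(rbind, out)
}
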