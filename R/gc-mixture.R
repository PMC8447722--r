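#' Per-read GC-content
#'
#' `100 * (G + C) / (A + C + G + T)` per sequence; ambiguous bases are
#' excluded from both numerator and denominator.  Reads consisting only
#' of ambiguous bases yield no value and are counted in the
#' `n_skipped` attribute.
#'
#' @param sequences Character vector of nucleotide sequences (or
#'   anything coercible with `as.character`, e.g. a
#'   `Biostrings::DNAStringSet`).
#' @return Numeric vector of %GC values, attribute `n_skipped`.
#' @export
read_gc <- function(sequences) {
  sequences <- as.character(sequences)
  if (length(sequences) == 0) {
    stop("`sequences` must be non-empty", call. = FALSE)
  }
  gc <- nchar(gsub("[^GCgc]", "", sequences))
  at <- nchar(gsub("[^ATat]", "", sequences))
  tot <- gc + at
  skip <- tot == 0
  out <- 100 * gc[!skip] / tot[!skip]
  attr(out, "n_skipped") <- sum(skip)
  out
}

# quantile-based initialization: component means at the (2i-1)/(2k)
# sample quantiles, pooled SD, equal weights
quantile_init <- function(x, k) {
  probs <- (2 * seq_len(k) - 1) / (2 * k)
  means <- as.numeric(stats::quantile(x, probs, names = FALSE))
  list(means = means, sds = rep(stats::sd(x), k), weights = rep(1 / k, k))
}

#' Fit a k-component univariate Gaussian mixture by EM
#'
#' Expectation-maximization for a mixture of `k` normal components,
#' used to decompose per-read GC-content distributions into discrete
#' genomic fractions.  Initialization is quantile-based (deterministic)
#' unless `init` is supplied.  The log-likelihood is non-decreasing
#' across iterations by construction and is recorded per iteration;
#' convergence is declared when the relative improvement drops below
#' `tol`.  With `fixed_components`, the component means and SDs are
#' held at the supplied values and only the weights are re-estimated —
#' the mode used to apply one population-wide mixture to each library.
#'
#' @param values Numeric vector of observations (at least `10 * k`,
#'   with nonzero variance).
#' @param k Number of components (default 3).
#' @param init Optional list with `means`, `sds`, `weights`.
#' @param max_iter Maximum EM iterations (default 1000).
#' @param tol Relative log-likelihood convergence tolerance (default
#'   1e-6).
#' @param fixed_components Optional list with `means` and `sds` to hold
#'   fixed (weights-only EM).
#' @return A `gc_mixture` object: `means`, `sds`, `weights` (sorted by
#'   ascending mean), `loglik`, `loglik_trace`, `n_iter`, `converged`,
#'   `k`, `n`.
#' @export
fit_gc_mixture <- function(values, k = 3, init = NULL, max_iter = 1000,
                           tol = 1e-6, fixed_components = NULL) {
  x <- as.numeric(values)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  if (length(x) < 10 * k) {
    stop("need at least 10 * k observations", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("input has zero variance; no mixture can be fitted",
         call. = FALSE)
  }
  fixed <- !is.null(fixed_components)
  if (fixed) {
    means <- fixed_components$means
    sds <- fixed_components$sds
    stopifnot(length(means) == k, length(sds) == k, all(sds > 0))
    weights <- if (!is.null(init$weights)) init$weights else rep(1 / k, k)
  } else if (!is.null(init)) {
    means <- init$means; sds <- init$sds; weights <- init$weights
    stopifnot(length(means) == k, length(sds) == k, length(weights) == k)
  } else {
    ini <- quantile_init(x, k)
    means <- ini$means; sds <- ini$sds; weights <- ini$weights
  }

  n <- length(x)
  loglik_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  dens <- matrix(0, n, k)
  while (iter < max_iter) {
    iter <- iter + 1L
    for (j in seq_len(k)) {
      dens[, j] <- weights[j] * stats::dnorm(x, means[j], sds[j])
    }
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_d))
    loglik_trace <- c(loglik_trace, ll)
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    weights <- nk / n
    if (!fixed) {
      means <- colSums(resp * x) / nk
      sds <- sqrt(colSums(resp * (x - rep(means, each = n))^2) / nk)
      sds <- pmax(sds, 1e-6)
    }
    if (is.finite(ll_old) &&
        (ll - ll_old) < tol * (abs(ll_old) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }

  ord <- order(means)
  structure(list(k = as.integer(k), means = means[ord], sds = sds[ord],
                 weights = weights[ord], loglik = loglik_trace[iter],
                 loglik_trace = loglik_trace, n_iter = iter,
                 converged = converged, n = n),
            class = "gc_mixture")
}

#' @export
print.gc_mixture <- function(x, ...) {
  cat(sprintf("<gc_mixture> k = %d, n = %d, loglik = %.2f (%s, %d iter)\n",
              x$k, x$n, x$loglik,
              if (x$converged) "converged" else "not converged", x$n_iter))
  print(data.frame(mean = x$means, sd = x$sds, weight = x$weights))
  invisible(x)
}

#' Per-library GC fraction report
#'
#' Collects the component weights of one fitted mixture per library
#' into a table, with components matched across libraries by ascending
#' mean (label-switching safe).  For `k = 3` the columns are named
#' `low`, `mid`, `high`.
#'
#' @param models Named list of `gc_mixture` objects (names = library
#'   ids), all with the same `k`.
#' @return Data.frame: `library_id`, one weight column per component,
#'   `converged`.
#' @export
fraction_report <- function(models) {
  ks <- vapply(models, `[[`, integer(1), "k")
  if (length(unique(ks)) != 1L) {
    stop("all models must have the same number of components",
         call. = FALSE)
  }
  k <- ks[[1]]
  comp_names <- if (k == 3) c("low", "mid", "high")
                else sprintf("comp%d", seq_len(k))
  w <- t(vapply(models, `[[`, numeric(k), "weights"))
  colnames(w) <- comp_names
  out <- data.frame(library_id = names(models), w,
                    converged = vapply(models, `[[`, logical(1),
                                       "converged"),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (any(!out$converged)) {
    warning("non-converged fits flagged in the report")
  }
  out
}

#' Correlate GC-fraction weights with genome size
#'
#' Pearson correlation of each component's per-library weight with the
#' libraries' 2C genome size.  In the study system, the low-GC
#' background fraction shrinks (relatively) with genome size while the
#' GC-elevated element fractions grow.
#'
#' @param report A [fraction_report()] table.
#' @param library_meta Data.frame with `library_id` and
#'   `genome_size_2c_mb`.
#' @return Data.frame: `component`, `r`, `p`, `undefined`.
#' @export
fraction_vs_genome_size <- function(report, library_meta) {
  meta <- library_meta[match(report$library_id, library_meta$library_id), ]
  if (anyNA(meta$library_id)) {
    stop("library metadata missing for some libraries", call. = FALSE)
  }
  if (nrow(report) < 4L) {
    stop("at least 4 libraries are required", call. = FALSE)
  }
  comps <- setdiff(names(report), c("library_id", "converged"))
  out <- lapply(comps, function(cc) {
    pc <- partial_cor(report[[cc]], meta$genome_size_2c_mb, NULL)
    data.frame(component = cc, r = pc$r, p = pc$p,
               undefined = pc$undefined, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
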