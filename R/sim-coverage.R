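#' Simulate a raw window coverage matrix
#'
#' Produces the windows-by-libraries matrix of mean per-base depth of
#' coverage the CNV analysis starts from.  The expected raw coverage of
#' a diploid window equals the library's mean exon coverage; an element
#' window in a clone carrying `c` copies has expectation
#' `(c/2) * exon_mean * gc_bias` (the GC-bias multiplier of the
#' library's prep batch applies only to windows whose GC exceeds the
#' configured threshold, reproducing the batch-wise coverage elevation
#' at high-GC CNV regions).  Multiplicative Gamma noise with mean 1 and
#' coefficient of variation `noise_dispersion` models read-depth
#' overdispersion; with dispersion 0 the matrix is deterministic and
#' downstream exon normalization returns exactly 2 on diploid windows
#' and exactly `c` on element windows.
#'
#' @param population A `clone_population` from [simulate_population()].
#' @param libraries Library metadata from [simulate_libraries()].
#' @param config A [sim_config()].
#' @param seed RNG seed.
#' @return List with `matrix` (raw `cov_matrix`) and `exon_mean`
#'   (named vector of per-library mean exon coverage).
#' @export
simulate_coverage_matrix <- function(population, libraries, config,
                                     seed = config$seed) {
  stopifnot(inherits(population, "clone_population"),
            inherits(config, "sim_config"))
  ws <- config$window_set
  n_win <- nrow(ws)
  n_lib <- nrow(libraries)
  el_ids <- names(config$element_windows)

  # per-window copy number per library's clone; diploid background = 2
  cn <- matrix(2, nrow = n_win, ncol = n_lib)
  clone_rows <- match(libraries$clone_id, population$clone_id)
  if (anyNA(clone_rows)) {
    stop("libraries refer to clones absent from the population",
         call. = FALSE)
  }
  for (e in el_ids) {
    idx <- config$element_windows[[e]]
    cn[idx, ] <- rep(population[[e]][clone_rows], each = length(idx))
  }

  biased <- config$window_gc > config$gc_bias_threshold
  exon_mean <- stats::setNames(libraries$exon_mean_coverage,
                               libraries$library_id)
  expected <- sweep(cn / 2, 2L, unname(exon_mean), "*")
  bias_mat <- matrix(1, n_win, n_lib)
  bias_mat[biased, ] <- rep(libraries$gc_bias, each = sum(biased))
  expected <- expected * bias_mat

  d <- config$noise_dispersion
  vals <- with_seed(seed, {
    if (d > 0) {
      shape <- 1 / d^2
      noise <- matrix(stats::rgamma(n_win * n_lib, shape = shape,
                                    rate = shape), n_win, n_lib)
      expected * noise
    } else {
      expected
    }
  })
  colnames(vals) <- libraries$library_id
  list(matrix = coverage_matrix(ws, vals, normalized = FALSE),
       exon_mean = exon_mean)
}
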