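# fixture builders shared across test files

# wrap a plain matrix (windows x libraries) as a cov_matrix on one contig
make_cov_matrix <- function(values, contig = "ctgA", window_size = 5000,
                            normalized = TRUE) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("L%02d", seq_len(ncol(values)))
  }
  lens <- stats::setNames(nrow(values) * window_size, contig)
  ws <- tile_windows(lens, window_size)
  coverage_matrix(ws, values, normalized = normalized)
}

# a diploid background matrix with variable segments implanted.
# segments: list of list(at = first window, copies = per-library copy
# numbers).  Everything gets N(0, noise_sd) additive noise.
make_cnv_fixture <- function(n_windows, n_lib, segments,
                             noise_sd = 0.05, seed = 1,
                             contig = "ctgA") {
  set.seed(seed)
  vals <- matrix(2, n_windows, n_lib)
  for (seg in segments) {
    idx <- seg$at:(seg$at + seg$len - 1L)
    vals[idx, ] <- rep(seg$copies, each = length(idx))
  }
  vals <- vals + matrix(stats::rnorm(length(vals), 0, noise_sd),
                        nrow(vals))
  vals <- pmax(vals, 0)
  make_cov_matrix(vals, contig = contig)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a deterministic clone population covering copy numbers 0..6 for every
# element of `config`, cycling with offsets so elements segregate
# independently
make_graded_population <- function(config) {
  el_ids <- vapply(config$elements, `[[`, character(1), "id")
  n <- config$n_clones
  cp <- sapply(seq_along(el_ids), function(j) {
    as.integer((seq_len(n) - 1L + 2L * (j - 1L)) %% 7L)
  })
  colnames(cp) <- el_ids
  pop <- data.frame(clone_id = sprintf("clone%02d", seq_len(n)), cp,
                    basal_2c_mb = config$basal_2c_mb,
                    stringsAsFactors = FALSE)
  pop$genome_size_2c_mb <- implied_2c(cp, config)
  class(pop) <- c("clone_population", "data.frame")
  attr(pop, "element_ids") <- el_ids
  pop
}
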