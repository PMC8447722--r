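#' Define a segregating genomic element
#'
#' An independently segregating element (ISE) is a megabase-scale block
#' of mostly satellite DNA that is present in 0 or more copies per clone
#' and behaves additively on genome size.  `size_mb` is the DNA content
#' of one copy; `gc_pct` its mean GC-content (satellite arrays here are
#' GC-elevated relative to the ~26% GC genomic background); `host` gives
#' the window footprint of the element on the toy reference assembly as
#' one or more ranges of within-contig window indices (1-based,
#' inclusive).
#'
#' @param id Element label.
#' @param size_mb Megabases per copy (> 0).
#' @param gc_pct Mean GC of the element sequence, in percent.
#' @param host Data.frame with columns `contig`, `from`, `to` (window
#'   indices within the contig).
#' @return An `element_def` list.
#' @export
element_def <- function(id, size_mb, gc_pct, host) {
  stop_if_not_scalar_pos(size_mb, "size_mb")
  if (!is.numeric(gc_pct) || gc_pct < 0 || gc_pct > 100) {
    stop("`gc_pct` must be in [0, 100]", call. = FALSE)
  }
  host <- as.data.frame(host)
  stopifnot(all(c("contig", "from", "to") %in% names(host)))
  if (any(host$from > host$to) || any(host$from < 1)) {
    stop("invalid host window ranges for element ", id, call. = FALSE)
  }
  # host ranges of one element must not overlap each other
  by_ctg <- split(host, host$contig)
  for (h in by_ctg) {
    h <- h[order(h$from), ]
    if (nrow(h) > 1 && any(h$from[-1] <= h$to[-nrow(h)])) {
      stop("overlapping host ranges for element ", id, call. = FALSE)
    }
  }
  structure(list(id = id, size_mb = size_mb, gc_pct = gc_pct, host = host),
            class = "element_def")
}

default_elements <- function() {
  list(
    element_def("ise34", size_mb = 34, gc_pct = 36,
                host = data.frame(contig = "ctg_b1", from = 1, to = 200)),
    element_def("ise17", size_mb = 17, gc_pct = 48,
                host = data.frame(contig = "ctg_b2", from = 1, to = 100)),
    element_def("ise05", size_mb = 0.51, gc_pct = 36,
                host = data.frame(contig = "ctg_core1", from = 101, to = 103))
  )
}

default_contig_lengths <- function() {
  c(ctg_core1 = 1.5e6, ctg_core2 = 1.0e6, ctg_core3 = 7.5e5,
    ctg_b1 = 1.0e6, ctg_b2 = 5.0e5)
}

#' Simulation configuration for a clonal rotifer-like population
#'
#' Fixes the study conditions the simulator emulates: a basal 2C genome
#' carried by every clone, a set of independently segregating elements
#' with additive genome-size effects and elevated GC, a toy reference
#' assembly tiled into coverage windows, multiplicative coverage noise,
#' and a per-prep-batch GC bias acting on high-GC windows.  Defaults
#' mirror the published study population: basal 2C of 414 Mb, elements
#' of up to 34 Mb per copy segregating in 0-6 copies across 15 clones
#' sequenced as 29 libraries in six prep batches.
#'
#' @param n_clones Number of clones (default 15).
#' @param elements List of [element_def()]s.
#' @param basal_2c_mb Basal 2C genome size in Mb shared by all clones.
#' @param window_size_bp Coverage window size in bp (default 5000).
#' @param contig_lengths Named vector of toy assembly contig lengths.
#' @param noise_dispersion Coefficient of variation of the multiplicative
#'   Gamma coverage noise (0 = noise-free).
#' @param gc_bias_sd Log-scale SD of the per-prep-batch GC-bias
#'   multiplier (0 = no bias).
#' @param gc_bias_threshold Windows with GC above this (%) receive the
#'   prep's GC-bias multiplier (default 32).
#' @param diploid_gc GC (%) assigned to diploid background windows.
#' @param seed Default seed used by simulator calls unless overridden.
#' @return A `sim_config` list, including the tiled `window_set`, a
#'   per-window GC vector and the per-element global window indices.
#' @export
sim_config <- function(n_clones = 15,
                       elements = default_elements(),
                       basal_2c_mb = 414,
                       window_size_bp = 5000,
                       contig_lengths = default_contig_lengths(),
                       noise_dispersion = 0.1,
                       gc_bias_sd = 0.08,
                       gc_bias_threshold = 32,
                       diploid_gc = 26,
                       seed = NULL) {
  stop_if_not_scalar_pos(n_clones, "n_clones")
  stop_if_not_scalar_pos(basal_2c_mb, "basal_2c_mb")
  stop_if_not_scalar_pos(window_size_bp, "window_size_bp")
  stopifnot(noise_dispersion >= 0, gc_bias_sd >= 0)
  ws <- tile_windows(contig_lengths, window_size_bp)

  window_gc <- rep(diploid_gc, nrow(ws))
  element_windows <- list()
  n_per_ctg <- table(ws$contig)
  occupied <- integer(0)
  for (el in elements) {
    stopifnot(inherits(el, "element_def"))
    idx <- integer(0)
    for (i in seq_len(nrow(el$host))) {
      h <- el$host[i, ]
      if (!h$contig %in% ws$contig) {
        stop("element ", el$id, " hosted on unknown contig ", h$contig,
             call. = FALSE)
      }
      if (h$to > n_per_ctg[[h$contig]]) {
        stop("element ", el$id, " exceeds windows of contig ", h$contig,
             call. = FALSE)
      }
      ctg_idx <- ws$index[ws$contig == h$contig]
      idx <- c(idx, ctg_idx[h$from:h$to])
    }
    if (any(idx %in% occupied)) {
      stop("element host ranges overlap between elements", call. = FALSE)
    }
    occupied <- c(occupied, idx)
    element_windows[[el$id]] <- idx
    window_gc[idx] <- el$gc_pct
  }

  structure(list(n_clones = as.integer(n_clones), elements = elements,
                 basal_2c_mb = basal_2c_mb, window_size_bp = window_size_bp,
                 contig_lengths = contig_lengths, window_set = ws,
                 window_gc = window_gc, element_windows = element_windows,
                 noise_dispersion = noise_dispersion,
                 gc_bias_sd = gc_bias_sd,
                 gc_bias_threshold = gc_bias_threshold,
                 diploid_gc = diploid_gc, seed = seed),
            class = "sim_config")
}

element_sizes <- function(config) {
  vapply(config$elements, function(e) e$size_mb, numeric(1),
         USE.NAMES = FALSE) |>
    stats::setNames(vapply(config$elements, `[[`, character(1), "id"))
}

#' Implied 2C genome size of genotypes
#'
#' Genome size is strictly additive: 2C = basal + sum over elements of
#' copy number times element size.
#'
#' @param copies Data.frame or matrix of per-element copy numbers
#'   (columns named by element id), or a named vector for one clone.
#' @param config A [sim_config()].
#' @return Numeric vector of 2C sizes in Mb.
#' @export
implied_2c <- function(copies, config) {
  sizes <- element_sizes(config)
  if (is.null(dim(copies))) copies <- t(as.matrix(copies))
  cp <- as.matrix(as.data.frame(copies)[, names(sizes), drop = FALSE])
  config$basal_2c_mb + as.numeric(cp %*% sizes)
}

#' Simulate a population of clone genotypes
#'
#' Each clone carries an independent copy number for every element,
#' drawn from a zero-inflated binomial (point mass at 0 with probability
#' 0.25, otherwise Binomial(6, 0.4)), giving the 0-6 copy range observed
#' in the study population with a realistic share of zero-copy clones.
#' Clone 1 is fixed to the all-zero basal genotype, mimicking the basal
#' clones at the population's minimum genome size.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return A `clone_population` data.frame: `clone_id`, one copy-number
#'   column per element, `basal_2c_mb`, `genome_size_2c_mb`.
#' @export
simulate_population <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  ids <- sprintf("clone%02d", seq_len(config$n_clones))
  el_ids <- names(element_sizes(config))
  with_seed(seed, {
    cp <- sapply(el_ids, function(e) {
      z <- stats::rbinom(config$n_clones, 1L, 0.25)
      n <- stats::rbinom(config$n_clones, 6L, 0.4)
      ifelse(z == 1L, 0L, n)
    })
    cp <- matrix(as.integer(cp), nrow = config$n_clones,
                 dimnames = list(NULL, el_ids))
    cp[1L, ] <- 0L
    pop <- data.frame(clone_id = ids, cp,
                      basal_2c_mb = config$basal_2c_mb,
                      stringsAsFactors = FALSE)
    pop$genome_size_2c_mb <- implied_2c(cp, config)
    class(pop) <- c("clone_population", "data.frame")
    attr(pop, "element_ids") <- el_ids
    pop
  })
}

#' Cross two clones
#'
#' Elements segregate independently during meiosis: each parental copy
#' is transmitted with probability 1/2, so offspring copy number per
#' element is Binomial(c_a, 1/2) + Binomial(c_b, 1/2) and the expected
#' offspring genome size is the midparent value.
#'
#' @param parent_a,parent_b Single rows of a `clone_population` (or
#'   named copy-number vectors over the same elements).
#' @param config A [sim_config()].
#' @param seed RNG seed.
#' @param clone_id Label for the offspring clone.
#' @return A one-row `clone_population` data.frame.
#' @export
cross <- function(parent_a, parent_b, config, seed = NULL,
                  clone_id = "offspring") {
  el_ids <- names(element_sizes(config))
  get_copies <- function(p) {
    if (is.data.frame(p)) p <- unlist(p[1, el_ids, drop = FALSE])
    if (!all(el_ids %in% names(p))) {
      stop("parents must carry copy numbers for the same elements",
           call. = FALSE)
    }
    as.integer(p[el_ids])
  }
  ca <- get_copies(parent_a)
  cb <- get_copies(parent_b)
  with_seed(seed, {
    off <- stats::rbinom(length(ca), ca, 0.5) +
      stats::rbinom(length(cb), cb, 0.5)
    cp <- matrix(as.integer(off), nrow = 1, dimnames = list(NULL, el_ids))
    pop <- data.frame(clone_id = clone_id, cp,
                      basal_2c_mb = config$basal_2c_mb,
                      stringsAsFactors = FALSE)
    pop$genome_size_2c_mb <- implied_2c(cp, config)
    class(pop) <- c("clone_population", "data.frame")
    attr(pop, "element_ids") <- el_ids
    pop
  })
}

#' Simulate sequencing-library metadata for a population
#'
#' Assigns 1-4 short-read libraries per clone following the study's
#' pattern (29 libraries over 15 clones), a prep batch A-F per library,
#' a mean exon coverage drawn log-normally around 30-fold (clipped to
#' the 10-79x range of realistic library depths), and the per-batch
#' GC-bias multiplier applied by [simulate_coverage_matrix()] to
#' high-GC windows.
#'
#' @param population A `clone_population`.
#' @param config A [sim_config()].
#' @param seed RNG seed.
#' @return Data.frame with columns `library_id`, `clone_id`,
#'   `prep_batch`, `genome_size_2c_mb`, `exon_mean_coverage`, `gc_bias`.
#' @export
simulate_libraries <- function(population, config, seed = config$seed) {
  stopifnot(inherits(population, "clone_population"))
  pattern <- c(2, 2, 2, 2, 1, 1, 2, 4, 2, 1, 2, 2, 2, 2, 2)
  n_clones <- nrow(population)
  counts <- rep_len(pattern, n_clones)
  with_seed(seed, {
    batch_mult <- stats::setNames(
      exp(stats::rnorm(6, 0, config$gc_bias_sd)), LETTERS[1:6])
    rows <- lapply(seq_len(n_clones), function(i) {
      k <- counts[i]
      batches <- sample(LETTERS[1:6], k, replace = TRUE)
      depth <- pmin(pmax(stats::rlnorm(k, log(30), 0.35), 10), 79)
      data.frame(
        library_id = sprintf("%s_L%d", population$clone_id[i], seq_len(k)),
        clone_id = population$clone_id[i],
        prep_batch = batches,
        genome_size_2c_mb = population$genome_size_2c_mb[i],
        exon_mean_coverage = depth,
        gc_bias = unname(batch_mult[batches]),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
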