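#' Default GC mixture generator parameters
#'
#' The three normal subpopulations of per-read GC values observed in the
#' study's pooled short reads: a broad low-GC background (26 +/- 6 %GC)
#' and two narrower GC-elevated fractions (36 +/- 2.5 and 48 +/- 3 %GC)
#' contributed mostly by satellite-rich elements.  `floor_mid` and
#' `floor_high` are the shares of the basal genome that fall into the
#' mid/high components even in element-free clones (the basal genome is
#' not GC-homogeneous).
#'
#' @return List with `means`, `sds`, `floor_mid`, `floor_high`.
#' @export
gc_mixture_defaults <- function() {
  list(means = c(26, 36, 48), sds = c(6, 2.5, 3),
       floor_mid = 0.10, floor_high = 0.03)
}

#' Mixture weights implied by a genotype
#'
#' The low-GC component mass is proportional to basal genome content;
#' the mid/high components get the configured basal floors plus the
#' genotype's element content, each element assigned to the component
#' whose mean is closest to its GC.
#'
#' @param genotype One row of a `clone_population` or named copy vector.
#' @param config A [sim_config()].
#' @param mixture Generator parameters, see [gc_mixture_defaults()].
#' @return Numeric weight vector summing to 1.
#' @export
gc_weights_for_genotype <- function(genotype, config,
                                    mixture = gc_mixture_defaults()) {
  el <- element_sizes(config)
  if (is.data.frame(genotype)) {
    copies <- unlist(genotype[1, names(el), drop = FALSE])
  } else {
    copies <- genotype[names(el)]
  }
  basal <- config$basal_2c_mb
  mass <- c(basal * (1 - mixture$floor_mid - mixture$floor_high),
            basal * mixture$floor_mid,
            basal * mixture$floor_high)
  for (e in config$elements) {
    comp <- which.min(abs(mixture$means - e$gc_pct))
    mass[comp] <- mass[comp] + copies[[e$id]] * e$size_mb
  }
  mass / sum(mass)
}

#' Simulate per-read GC values for one clone
#'
#' Draws read GC percentages from the three-component normal mixture
#' whose weights are implied by the clone's genotype (see
#' [gc_weights_for_genotype()]): clones with more element copies shift
#' read mass from the low-GC background into the GC-elevated fractions.
#' Values are clipped to `[0, 100]`.
#'
#' @param genotype One row of a `clone_population` (or named copy
#'   vector).
#' @param config A [sim_config()].
#' @param n_reads Number of reads to draw (> 0).
#' @param seed RNG seed.
#' @param mixture Generator parameters, see [gc_mixture_defaults()].
#' @return Numeric vector of %GC values with attributes `weights` (the
#'   generating weights) and `component` (per-read component index).
#' @export
simulate_gc_reads <- function(genotype, config, n_reads,
                              seed = config$seed,
                              mixture = gc_mixture_defaults()) {
  stop_if_not_scalar_pos(n_reads, "n_reads")
  w <- gc_weights_for_genotype(genotype, config, mixture)
  with_seed(seed, {
    comp <- sample.int(length(w), n_reads, replace = TRUE, prob = w)
    x <- stats::rnorm(n_reads, mixture$means[comp], mixture$sds[comp])
    x <- pmin(pmax(x, 0), 100)
    attr(x, "weights") <- w
    attr(x, "component") <- comp
    x
  })
}
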