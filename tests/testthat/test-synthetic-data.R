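test_that("genome size is strictly additive in element copies", {
  cfg <- sim_config(seed = 1)
  # zero copies of everything -> basal 2C
  zero <- stats::setNames(rep(0L, 3), c("ise34", "ise17", "ise05"))
  expect_equal(implied_2c(zero, cfg), cfg$basal_2c_mb)
  # a 2 x 207 Mb core plus 4 copies of a 34-Mb element
  four <- stats::setNames(c(4L, 0L, 0L), c("ise34", "ise17", "ise05"))
  expect_equal(implied_2c(four, sim_config(basal_2c_mb = 414)), 550)
  # additivity over a whole population
  pop <- simulate_population(cfg)
  cp <- as.matrix(as.data.frame(pop)[, c("ise34", "ise17", "ise05")])
  sizes <- c(ise34 = 34, ise17 = 17, ise05 = 0.51)
  expect_equal(pop$genome_size_2c_mb,
               cfg$basal_2c_mb + as.numeric(cp %*% sizes))
})

test_that("simulator output is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 11)
  expect_identical(simulate_population(cfg), simulate_population(cfg))
  pop <- simulate_population(cfg)
  libs <- simulate_libraries(pop, cfg)
  expect_identical(libs, simulate_libraries(pop, cfg))
  expect_identical(simulate_coverage_matrix(pop, libs, cfg),
                   simulate_coverage_matrix(pop, libs, cfg))
  g <- pop[3, ]
  expect_identical(as.numeric(simulate_gc_reads(g, cfg, 1000, seed = 5)),
                   as.numeric(simulate_gc_reads(g, cfg, 1000, seed = 5)))
  expect_identical(simulate_ddpcr(4, seed = 9), simulate_ddpcr(4, seed = 9))
})

test_that("population draws include zero-copy clones and valid copies", {
  cfg <- sim_config(n_clones = 40, seed = 2)
  pop <- simulate_population(cfg)
  cp <- as.matrix(as.data.frame(pop)[, attr(pop, "element_ids")])
  expect_true(all(cp >= 0 & cp <= 6))
  expect_true(all(cp[1, ] == 0))  # forced basal clone
  expect_gt(sum(cp == 0), 0)
})

test_that("crosses transmit each copy independently with probability 1/2", {
  cfg <- sim_config(seed = 3)
  el <- c("ise34", "ise17", "ise05")
  p6 <- stats::setNames(c(6L, 0L, 0L), el)
  p0 <- stats::setNames(c(0L, 0L, 0L), el)
  # 6 x 0 cross: offspring expectation 3 (the observed IK1-style value)
  off <- with(list(), {
    set.seed(101)
    vapply(1:10000, function(i) cross(p6, p0, cfg)$ise34, numeric(1))
  })
  se <- sd(off) / sqrt(length(off))
  expect_lt(abs(mean(off) - 3), 3 * se)
  # 0 x 0 -> always 0
  zz <- vapply(1:50, function(i) cross(p0, p0, cfg)$ise34, numeric(1))
  expect_true(all(zz == 0))
  # 4 x 2 cross: midparent expectation 3
  p4 <- stats::setNames(c(4L, 0L, 0L), el)
  p2 <- stats::setNames(c(2L, 0L, 0L), el)
  set.seed(202)
  off42 <- vapply(1:10000, function(i) cross(p4, p2, cfg)$ise34,
                  numeric(1))
  expect_lt(abs(mean(off42) - 3), 3 * sd(off42) / sqrt(length(off42)))
  # mismatched element universes error
  expect_error(cross(stats::setNames(2L, "other"), p0, cfg),
               "same elements")
})

test_that("noise-free coverage recovers copy number exactly after normalization", {
  cfg <- sim_config(noise_dispersion = 0, gc_bias_sd = 0, seed = 4)
  pop <- simulate_population(cfg)
  libs <- simulate_libraries(pop, cfg)
  sim <- simulate_coverage_matrix(pop, libs, cfg)
  nm <- normalize_coverage(sim$matrix, sim$exon_mean)
  el_win <- unlist(cfg$element_windows)
  dip <- setdiff(seq_len(nrow(nm$values)), el_win)
  expect_true(all(nm$values[dip, ] == 2))  # exactly 2, no tolerance
  for (e in names(cfg$element_windows)) {
    idx <- cfg$element_windows[[e]]
    for (j in seq_len(nrow(libs))) {
      cn <- pop[[e]][pop$clone_id == libs$clone_id[j]]
      # odd copy numbers can sit one ulp off after the multiply/divide
      expect_equal(unique(nm$values[idx, j]), cn, tolerance = 1e-12)
    }
  }
  # zero-copy clone -> element windows at exactly 0
  lib1 <- which(libs$clone_id == "clone01")[1]
  expect_true(all(nm$values[el_win, lib1] == 0))
})

test_that("GC-read component frequencies match the genotype-implied weights", {
  cfg <- sim_config(seed = 6)
  pop <- make_graded_population(cfg)
  g_big <- pop[which.max(pop$genome_size_2c_mb), ]
  x <- simulate_gc_reads(g_big, cfg, 100000, seed = 7)
  w <- attr(x, "weights")
  counts <- tabulate(attr(x, "component"), 3)
  se <- sqrt(w * (1 - w) / 100000)
  expect_true(all(abs(counts / 100000 - w) < 3 * se))
  expect_true(all(x >= 0 & x <= 100))
  # element-free genotype: mid/high weights at their configured floors
  g0 <- stats::setNames(rep(0L, 3), c("ise34", "ise17", "ise05"))
  w0 <- attr(simulate_gc_reads(g0, cfg, 100, seed = 8), "weights")
  mx <- gc_mixture_defaults()
  expect_equal(unname(w0), c(1 - mx$floor_mid - mx$floor_high,
                             mx$floor_mid, mx$floor_high))
  expect_error(simulate_gc_reads(g0, cfg, 0), "n_reads")
})

test_that("ddPCR emulation recovers copy number", {
  # zero-copy locus: target concentration 0, estimated CN 0
  r0 <- simulate_ddpcr(0, seed = 1)
  expect_equal(r0$conc[r0$channel == "T"], 0)
  expect_equal(ddpcr_cn_from_readout(r0)$cn, 0)
  # diploid locus at large droplet count converges to CN 2
  r2 <- simulate_ddpcr(2, n_droplets = 2e6, seed = 2)
  expect_lt(abs(ddpcr_cn_from_readout(r2)$cn - 2), 0.05)
  # six copies recovered within the 95% CI at 15,000 droplets
  r6 <- simulate_ddpcr(6, n_droplets = 15000, seed = 3)
  est <- ddpcr_cn_from_readout(r6)
  expect_gte(6, est$ci[1])
  expect_lte(6, est$ci[2])
})
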