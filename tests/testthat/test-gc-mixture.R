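test_that("read GC is computed on unambiguous bases only", {
  gc <- read_gc(c("ATGC", "AAAA", "GGCC", "ANNGT", "NNN"))
  expect_equal(as.numeric(gc), c(50, 0, 100, 100 / 3))
  expect_equal(attr(gc, "n_skipped"), 1L)
  expect_error(read_gc(character(0)), "non-empty")
})

test_that("k = 1 EM reduces to the sample mean and SD", {
  set.seed(10)
  x <- rnorm(500, 30, 4)
  fit <- fit_gc_mixture(x, k = 1)
  expect_equal(fit$means, mean(x), tolerance = 1e-6)
  # EM uses the maximum-likelihood (1/n) variance
  expect_equal(fit$sds, sd(x) * sqrt(499 / 500), tolerance = 1e-6)
  expect_equal(fit$weights, 1)
})

test_that("EM log-likelihood is non-decreasing on assorted inputs", {
  set.seed(11)
  for (i in 1:5) {
    x <- c(rnorm(300, 25, 5), rnorm(200, 40, 3), runif(100, 0, 100))
    fit <- fit_gc_mixture(x, k = 3)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
    expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
    expect_true(all(diff(fit$means) >= 0))  # sorted ascending
  }
})

test_that("EM recovers the three GC fractions of the read mixture", {
  set.seed(12)
  n <- 100000
  comp <- sample.int(3, n, TRUE)
  x <- rnorm(n, c(26, 36, 48)[comp], c(6, 2.5, 3)[comp])
  fit <- fit_gc_mixture(x, k = 3)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$means - c(26, 36, 48))), 1)
})

test_that("EM agrees with an independent mixture fitter on a fixture", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))  # Mclust resolves helpers unqualified
  set.seed(13)
  x <- c(rnorm(3000, 26, 6), rnorm(3000, 36, 2.5), rnorm(3000, 48, 3))
  fit <- fit_gc_mixture(x, k = 3, tol = 1e-9)
  mc <- Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.05)
})

test_that("degenerate mixture inputs are rejected", {
  expect_error(fit_gc_mixture(rep(5, 100)), "zero variance")
  expect_error(fit_gc_mixture(rnorm(100), k = 0), "k")
  expect_error(fit_gc_mixture(rnorm(5), k = 3), "10 \\* k")
})

test_that("fixed-component fits re-estimate only the weights", {
  set.seed(14)
  x <- c(rnorm(2000, 26, 6), rnorm(500, 36, 2.5), rnorm(250, 48, 3))
  fit <- fit_gc_mixture(x, k = 3,
                        fixed_components = list(means = c(26, 36, 48),
                                                sds = c(6, 2.5, 3)))
  expect_equal(fit$means, c(26, 36, 48))
  expect_equal(fit$sds, c(6, 2.5, 3))
  expect_equal(fit$weights, c(2000, 500, 250) / 2750, tolerance = 0.05)
})

test_that("fraction report aligns components across libraries", {
  cfg <- sim_config(seed = 15)
  pop <- make_graded_population(cfg)
  fixed <- list(means = c(26, 36, 48), sds = c(6, 2.5, 3))
  models <- list(
    small = fit_gc_mixture(simulate_gc_reads(pop[1, ], cfg, 20000,
                                             seed = 1),
                           fixed_components = fixed),
    big = fit_gc_mixture(simulate_gc_reads(pop[7, ], cfg, 20000,
                                           seed = 2),
                         fixed_components = fixed))
  rep <- fraction_report(models)
  expect_equal(names(rep), c("library_id", "low", "mid", "high",
                             "converged"))
  expect_equal(rowSums(rep[, c("low", "mid", "high")]), c(1, 1),
               tolerance = 1e-9, ignore_attr = TRUE)
  # element-free clone is dominated by the low-GC fraction
  expect_gt(rep$low[rep$library_id == "small"],
            max(rep$mid[1], rep$high[1]))
  # identical inputs give identical rows
  m2 <- list(a = models$small, b = models$small)
  r2 <- fraction_report(m2)
  expect_equal(unlist(r2[1, -1]), unlist(r2[2, -1]))
})

test_that("fraction weights correlate with genome size in the expected directions", {
  cfg <- sim_config(seed = 16)
  pop <- make_graded_population(cfg)
  fixed <- list(means = c(26, 36, 48), sds = c(6, 2.5, 3))
  models <- lapply(seq_len(nrow(pop)), function(i) {
    fit_gc_mixture(simulate_gc_reads(pop[i, ], cfg, 20000, seed = i),
                   fixed_components = fixed)
  })
  names(models) <- paste0(pop$clone_id, "_L1")
  rep <- fraction_report(models)
  meta <- data.frame(library_id = names(models),
                     genome_size_2c_mb = pop$genome_size_2c_mb)
  corr <- fraction_vs_genome_size(rep, meta)
  expect_lt(corr$r[corr$component == "low"], 0)
  expect_gt(corr$r[corr$component == "mid"], 0)
  expect_gt(corr$r[corr$component == "high"], 0)
  # perfect linear weight-size relation -> r = 1
  rep_lin <- data.frame(library_id = meta$library_id,
                        low = (meta$genome_size_2c_mb - 400) / 300)
  expect_equal(fraction_vs_genome_size(rep_lin, meta)$r, 1,
               tolerance = 1e-9)
})
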