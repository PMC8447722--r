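test_that("a constant diploid matrix yields no CNVs", {
  m <- make_cov_matrix(matrix(2, 30, 6))
  cnvs <- detect_cnvs(m)
  expect_equal(nrow(cnvs), 0L)
})

test_that("an implanted 10-window copy-number segment is called as one CNV", {
  copies <- c(0, 0, 2, 3, 4, 6)
  m <- make_cnv_fixture(30, 6, list(list(at = 11, len = 10,
                                         copies = copies)), seed = 5)
  cnvs <- detect_cnvs(m)
  expect_equal(nrow(cnvs), 1L)
  expect_equal(cnvs$first_win, 11)
  expect_equal(cnvs$last_win, 20)
  expect_equal(cnvs$placement, "internal")
  # per-library mean coverage tracks the implanted copy numbers
  lib_cov <- attr(cnvs, "lib_coverage")
  expect_equal(as.numeric(lib_cov), copies, tolerance = 0.1)
})

test_that("segments shorter than min_windows are suppressed", {
  copies <- c(0, 0, 2, 3, 4, 6)
  m2 <- make_cnv_fixture(30, 6, list(list(at = 11, len = 2,
                                          copies = copies)), seed = 6)
  expect_equal(nrow(detect_cnvs(m2)), 0L)
  m3 <- make_cnv_fixture(30, 6, list(list(at = 11, len = 3,
                                          copies = copies)), seed = 7)
  expect_equal(nrow(detect_cnvs(m3)), 1L)
})

test_that("unnormalized input is rejected", {
  m <- make_cov_matrix(matrix(2, 30, 6), normalized = FALSE)
  expect_error(detect_cnvs(m), "normalized")
})

test_that("detector matches the brute-force oracle on small fixtures", {
  params <- detector_params(correlation = "pearson")
  for (seed in 1:30) {
    vals <- random_detector_fixture(seed)
    m <- make_cov_matrix(vals)
    got <- detect_cnvs(m, params)
    want <- oracle_detect_contig(vals)
    expect_equal(nrow(got), nrow(want), info = paste("fixture", seed))
    if (nrow(want) > 0) {
      expect_equal(got$first_win, want$first, info = paste("fixture", seed))
      expect_equal(got$last_win, want$last, info = paste("fixture", seed))
    }
  }
})

test_that("raising the SD threshold never increases total CNV bp", {
  vals <- random_detector_fixture(77)
  m <- make_cov_matrix(vals)
  thresholds <- c(0.3, 0.7, 1.5, 2.5)
  bp <- vapply(thresholds, function(th) {
    cn <- detect_cnvs(m, detector_params(sd_threshold = th,
                                         correlation = "pearson"))
    if (nrow(cn) == 0) 0 else sum(cn$end - cn$start)
  }, numeric(1))
  expect_true(all(diff(bp) <= 0))
})

test_that("detection is deterministic", {
  vals <- random_detector_fixture(12)
  m <- make_cov_matrix(vals)
  expect_identical(detect_cnvs(m), detect_cnvs(m))
})

test_that("breakpoint bridging merges runs separated by one window", {
  # two correlated variable segments separated by a single quiet window
  set.seed(31)
  copies <- c(0, 1, 2, 4, 5, 6)
  vals <- matrix(2, 20, 6)
  vals[5:8, ] <- rep(copies, each = 4)
  vals[10:13, ] <- rep(copies, each = 4)
  vals <- pmax(vals + matrix(rnorm(120, 0, 0.05), 20), 0)
  cnvs <- detect_cnvs(make_cov_matrix(vals))
  expect_equal(nrow(cnvs), 1L)
  expect_equal(cnvs$first_win, 5)
  expect_equal(cnvs$last_win, 13)
})

test_that("contig edge windows merge into a neighboring CNV", {
  set.seed(32)
  copies <- c(0, 0, 2, 3, 4, 6)
  vals <- matrix(2, 12, 6)
  vals[2:6, ] <- rep(copies, each = 5)
  vals <- pmax(vals + matrix(rnorm(72, 0, 0.05), 12), 0)
  cnvs <- detect_cnvs(make_cov_matrix(vals))
  expect_equal(nrow(cnvs), 1L)
  expect_equal(cnvs$first_win, 1)  # deviant first window absorbed
  expect_equal(cnvs$placement, "contig-edge")
})

test_that("B-contig classification applies the 90/95% thresholds", {
  ws <- tile_windows(c(a = 100000, b = 100000, c = 100000), 5000)
  cnvs <- data.frame(cnv_id = c("CNV1", "CNV2", "CNV3"),
                     contig = c("a", "b", "c"),
                     start = c(0, 0, 0), end = c(100000, 50000, 92000),
                     stringsAsFactors = FALSE)
  bc <- classify_b_contigs(cnvs, ws)
  expect_equal(bc$is_b90, c(TRUE, FALSE, TRUE))
  expect_equal(bc$is_b95, c(TRUE, FALSE, FALSE))
  expect_equal(bc$cnv_fraction, c(1, 0.5, 0.92))
})

test_that("CNV summary reports count, fraction and N50", {
  one <- data.frame(contig = "a", start = 0, end = 10000)
  s1 <- cnv_summary(one, 1e6)
  expect_equal(s1$n50_bp, 10000)
  expect_equal(s1$count, 1L)
  lens <- data.frame(contig = "a", start = c(0, 10, 20, 30),
                     end = c(4, 13, 22, 31))
  expect_equal(cnv_summary(lens, 100)$n50_bp, 3)
  two <- data.frame(contig = "a", start = c(0, 50000),
                    end = c(21000, 60000))
  expect_equal(cnv_summary(two, 1e5)$assembly_fraction, 0.31)
  s0 <- cnv_summary(one[0, ], 1e6)
  expect_equal(s0$count, 0L)
  expect_equal(s0$n50_bp, 0)
})

test_that("placement distinguishes whole-contig, edge and internal CNVs", {
  ws <- tile_windows(c(a = 50000), 5000)
  whole <- data.frame(contig = "a", first_win = 1, last_win = 10)
  edge <- data.frame(contig = "a", first_win = 1, last_win = 4)
  internal <- data.frame(contig = "a", first_win = 3, last_win = 7)
  expect_equal(cnv_placement(whole, ws), "whole-contig")
  expect_equal(cnv_placement(edge, ws), "contig-edge")
  expect_equal(cnv_placement(internal, ws), "internal")
})
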