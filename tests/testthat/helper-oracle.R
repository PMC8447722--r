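# Brute-force re-implementation of the window-merging rules, written as
# a direct rule-by-rule scan over boolean state vectors so the package's
# run-based detector can be checked against it on small instances.
# Returns a data.frame(first, last) of window positions per call (single
# contig), or zero rows.
oracle_detect_contig <- function(V, sd_threshold = 0.7, alpha = 0.05,
                                 min_windows = 3, batch = NULL) {
  W <- nrow(V)
  n <- ncol(V)

  # residualize each window vector on the batch factor (or just center)
  resid_of <- function(v) {
    if (is.null(batch)) v - mean(v)
    else stats::residuals(stats::lm(v ~ factor(batch)))
  }
  E <- t(apply(V, 1, resid_of))
  q <- if (is.null(batch)) 0L else nlevels(factor(batch)) - 1L
  df <- n - 2L - q

  sig <- function(i, j) {
    a <- E[i, ]; b <- E[j, ]
    if (sd(a) == 0 || sd(b) == 0) return(FALSE)
    r <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    r <- max(-1, min(1, r))
    if (abs(r) == 1) return(TRUE)
    tv <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tv), df) < alpha
  }

  sds <- apply(V, 1, sd)
  seed <- sds > sd_threshold

  # criterion 1+2: window i and i+1 in same CNV iff both seeds and
  # significantly correlated; grow group labels left to right
  grp <- rep(NA_integer_, W)
  g <- 0L
  for (i in seq_len(W)) {
    if (!seed[i]) next
    if (i > 1L && seed[i - 1L] && !is.na(grp[i - 1L]) && sig(i - 1L, i)) {
      grp[i] <- grp[i - 1L]
    } else {
      g <- g + 1L
      grp[i] <- g
    }
  }

  runs <- function(grp) {
    out <- list()
    for (gg in unique(grp[!is.na(grp)])) {
      w <- which(grp == gg)
      out[[length(out) + 1L]] <- c(min(w), max(w))
    }
    out[order(vapply(out, `[[`, numeric(1), 1))]
  }
  rs <- runs(grp)

  # criterion 3: terminal windows join the neighboring CNV; a stranded
  # singleton at the very edge is absorbed into it
  if (length(rs) > 0) {
    starts <- vapply(rs, `[[`, numeric(1), 1)
    ends <- vapply(rs, `[[`, numeric(1), 2)
    if (any(starts == 2)) {
      k <- which(starts == 2)
      drop <- which(starts == 1 & ends == 1)
      if (length(drop) == 1) rs[[drop]] <- NULL
      k <- which(vapply(rs, `[[`, numeric(1), 1) == 2)
      rs[[k]][1] <- 1
    }
    starts <- vapply(rs, `[[`, numeric(1), 1)
    ends <- vapply(rs, `[[`, numeric(1), 2)
    if (any(ends == W - 1)) {
      drop <- which(starts == W & ends == W)
      if (length(drop) == 1) rs[[drop]] <- NULL
      k <- which(vapply(rs, `[[`, numeric(1), 2) == W - 1)
      rs[[k]][2] <- W
    }
  }

  # criterion 4: bridge single-window breakpoints until nothing changes
  changed <- TRUE
  while (changed && length(rs) > 1) {
    changed <- FALSE
    for (k in seq_len(length(rs) - 1L)) {
      if (rs[[k + 1L]][1] - rs[[k]][2] == 2L &&
          sig(rs[[k]][2], rs[[k + 1L]][1])) {
        rs[[k]] <- c(rs[[k]][1], rs[[k + 1L]][2])
        rs[[k + 1L]] <- NULL
        changed <- TRUE
        break
      }
    }
  }

  # criterion 5
  rs <- Filter(function(r) r[2] - r[1] + 1 >= min_windows, rs)
  if (length(rs) == 0) {
    return(data.frame(first = integer(0), last = integer(0)))
  }
  data.frame(first = vapply(rs, `[[`, numeric(1), 1),
             last = vapply(rs, `[[`, numeric(1), 2))
}

# random single-contig fixture generator for the oracle comparison:
# diploid background with random variable segments (random lengths,
# including 1- and 2-window ones, some separated by 1-window gaps)
random_detector_fixture <- function(seed) {
  set.seed(seed)
  W <- sample(10:50, 1)
  n_lib <- sample(c(6, 8, 12), 1)
  vals <- matrix(2, W, n_lib)
  pos <- 1L
  while (pos <= W - 1L) {
    if (runif(1) < 0.35) {
      len <- sample(1:6, 1)
      len <- min(len, W - pos + 1L)
      copies <- sample(0:6, n_lib, replace = TRUE)
      if (diff(range(copies)) >= 2) {
        vals[pos:(pos + len - 1L), ] <- rep(copies, each = len)
      }
      pos <- pos + len + sample(0:2, 1)
    } else {
      pos <- pos + sample(1:4, 1)
    }
  }
  vals <- pmax(vals + matrix(rnorm(W * n_lib, 0, 0.05), W), 0)
  vals
}
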