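#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so simulator calls never perturb an analysis session.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  invisible(x)
}

# Pearson correlation of x and y after regressing both on the covariate
# data.frame Z (factors expanded to dummies).  Returns r, the two-sided
# p from the t-transform with df = n - 2 - q, and q itself.  With Z NULL
# this is a plain Pearson correlation test.
partial_cor <- function(x, y, Z = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(Z)) {
    q <- 0L
    rx <- x - mean(x)
    ry <- y - mean(y)
  } else {
    Z <- as.data.frame(Z)
    mm <- stats::model.matrix(~., data = Z)
    q <- qr(mm)$rank - 1L
    rx <- stats::lm.fit(mm, x)$residuals
    ry <- stats::lm.fit(mm, y)$residuals
  }
  sx <- sqrt(sum(rx^2))
  sy <- sqrt(sum(ry^2))
  if (sx == 0 || sy == 0) {
    return(list(r = NA_real_, p = NA_real_, df = n - 2L - q, undefined = TRUE))
  }
  r <- sum(rx * ry) / (sx * sy)
  r <- max(-1, min(1, r))
  df <- n - 2L - q
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  if (abs(r) == 1) tval <- sign(r) * Inf
  p <- 2 * stats::pt(-abs(tval), df = df)
  list(r = r, p = p, df = df, undefined = FALSE)
}

# Projection residual-maker for a covariate data.frame: returns the
# symmetric (I - H) matrix so whole coverage matrices can be residualized
# with one matrix product.
residual_projector <- function(Z, n) {
  if (is.null(Z)) {
    J <- matrix(1 / n, n, n)
    return(list(M = diag(n) - J, q = 0L))
  }
  Z <- as.data.frame(Z)
  mm <- stats::model.matrix(~., data = Z)
  H <- mm %*% solve(crossprod(mm), t(mm))
  list(M = diag(n) - H, q = qr(mm)$rank - 1L)
}
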