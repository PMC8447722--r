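#' Simulate a droplet digital PCR readout for one locus
#'
#' Emulates standard ddPCR quantification: template molecules partition
#' into droplets with Poisson occupancy, a droplet is negative with
#' probability `exp(-lambda)`, and the amplicon concentration is
#' recovered as `-log(fraction negative) / droplet_volume`.  The two
#' reference channels correspond to diploid loci (2 copies); the target
#' channel's mean occupancy scales with `true_cn / 2`.  95% confidence
#' intervals come from the delta-method standard error of
#' `-log(p_neg)`.
#'
#' @param true_cn True integer copy number of the target locus (>= 0).
#' @param n_droplets Number of accepted droplets (> 0, typically
#'   10000-20000).
#' @param seed RNG seed.
#' @param lambda_ref Mean target molecules per droplet for a diploid
#'   locus (default 0.8, a typical ddPCR loading).
#' @param droplet_volume_ul Droplet volume in microliters (default
#'   0.85 nl), converting occupancy to copies/ul.
#' @return Data.frame with one row per channel (`T`, `R1`, `R2`):
#'   `conc`, `conc_lo`, `conc_hi` (copies/ul), `n_droplets`,
#'   `n_negative`.
#' @export
simulate_ddpcr <- function(true_cn, n_droplets = 15000, seed = NULL,
                           lambda_ref = 0.8, droplet_volume_ul = 0.00085) {
  if (!is.numeric(true_cn) || length(true_cn) != 1L || true_cn < 0) {
    stop("`true_cn` must be a single non-negative number", call. = FALSE)
  }
  stop_if_not_scalar_pos(n_droplets, "n_droplets")
  lambdas <- c(T = true_cn / 2 * lambda_ref,
               R1 = lambda_ref, R2 = lambda_ref)
  with_seed(seed, {
    rows <- lapply(names(lambdas), function(ch) {
      lam <- lambdas[[ch]]
      n_neg <- stats::rbinom(1L, n_droplets, exp(-lam))
      # all-positive plates cannot be quantified; cap at one negative
      n_neg <- max(n_neg, 1L)
      p_neg <- n_neg / n_droplets
      lam_hat <- -log(p_neg)
      se <- sqrt((1 - p_neg) / (n_droplets * p_neg))
      data.frame(channel = ch,
                 conc = lam_hat / droplet_volume_ul,
                 conc_lo = max(lam_hat - 1.96 * se, 0) / droplet_volume_ul,
                 conc_hi = (lam_hat + 1.96 * se) / droplet_volume_ul,
                 n_droplets = n_droplets, n_negative = n_neg,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
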