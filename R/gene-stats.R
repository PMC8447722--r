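#' Gene membership in a region set
#'
#' A gene belongs to a region when its midpoint falls inside one of the
#' region's intervals (default rule), or alternatively when at least
#' `overlap_frac` of its length overlaps the region.
#'
#' @param genes Data.frame with columns `contig`, `start`, `end`,
#'   `gene_id` (0-based half-open coordinates).
#' @param regions A `region_set`.
#' @param rule `"midpoint"` (default) or `"overlap"`.
#' @param overlap_frac Minimum overlap fraction for the `"overlap"`
#'   rule (default 0.5).
#' @param contigs Optional character vector naming the contig universe;
#'   genes on contigs outside it are counted outside with a warning.
#' @return Logical membership vector with attribute `count`.
#' @export
genes_in_regions <- function(genes, regions, rule = c("midpoint",
                                                      "overlap"),
                             overlap_frac = 0.5, contigs = NULL) {
  rule <- match.arg(rule)
  if (!is.null(contigs)) {
    off <- !genes$contig %in% contigs
    if (any(off)) {
      warning(sum(off), " gene(s) on contigs outside the region",
              " universe; counted outside")
    }
  }
  member <- logical(nrow(genes))
  if (rule == "midpoint") {
    mid <- floor((genes$start + genes$end) / 2)
    for (ctg in unique(genes$contig)) {
      reg <- regions[regions$contig == ctg, , drop = FALSE]
      gi <- which(genes$contig == ctg)
      if (nrow(reg) == 0) next
      reg <- reg[order(reg$start), ]
      # half-open membership: start <= mid < end
      pos <- findInterval(mid[gi], reg$start)
      ok <- pos >= 1 & pos <= nrow(reg)
      ok[ok] <- mid[gi][ok] < reg$end[pos[ok]]
      member[gi] <- ok
    }
  } else {
    for (ctg in unique(genes$contig)) {
      reg <- regions[regions$contig == ctg, , drop = FALSE]
      gi <- which(genes$contig == ctg)
      if (nrow(reg) == 0) next
      ig <- IRanges::IRanges(genes$start[gi] + 1, genes$end[gi])
      ir <- IRanges::reduce(IRanges::IRanges(reg$start + 1, reg$end))
      ov <- IRanges::findOverlaps(ig, ir)
      ov_bp <- IRanges::width(IRanges::pintersect(
        ig[S4Vectors::queryHits(ov)], ir[S4Vectors::subjectHits(ov)]))
      tot <- tapply(ov_bp, S4Vectors::queryHits(ov), sum)
      idx <- as.integer(names(tot))
      member[gi[idx]] <- tot / IRanges::width(ig[idx]) >= overlap_frac
    }
  }
  attr(member, "count") <- sum(member)
  member
}

# Fast midpoint-in-region membership for permutation nulls: regions are
# flattened to global coordinates so one findInterval serves all
# contigs.  Returns a closure mapping (contig index, 0-based position)
# to membership.
region_lookup <- function(regions, contig_lengths) {
  ctgs <- names(contig_lengths)
  offsets <- c(0, cumsum(as.numeric(contig_lengths)))[seq_along(ctgs)]
  names(offsets) <- ctgs
  reg <- regions[regions$contig %in% ctgs, , drop = FALSE]
  if (nrow(reg) == 0) {
    bounds <- numeric(0)
  } else {
    gs <- offsets[reg$contig] + reg$start
    ge <- offsets[reg$contig] + reg$end
    ord <- order(gs)
    bounds <- as.numeric(rbind(gs[ord], ge[ord]))
  }
  list(offsets = offsets,
       member = function(ctg_idx, pos) {
         if (length(bounds) == 0) return(rep(FALSE, length(pos)))
         g <- offsets[ctg_idx] + pos
         findInterval(g, bounds) %% 2 == 1
       })
}

perm_p_value <- function(observed, null, alternative) {
  n_perm <- length(null)
  p_ge <- (1 + sum(null >= observed)) / (n_perm + 1)
  p_le <- (1 + sum(null <= observed)) / (n_perm + 1)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

#' Monte Carlo permutation test for gene density in regions
#'
#' Tests whether the observed number of genes inside a region set (CNV
#' regions, typically) departs from a null in which every gene is
#' re-placed uniformly at random in the assembly — preserving its
#' length and staying within one contig, with contigs chosen in
#' proportion to the number of valid start positions.  The default
#' alternative `"less"` asks whether regions are gene-poor.  The
#' empirical p-value uses the plus-one correction and is therefore
#' never zero.
#'
#' @param genes Gene table (`contig`, `start`, `end`, `gene_id`).
#' @param regions A `region_set`.
#' @param contig_lengths Named vector of contig lengths.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @param alternative `"less"`, `"greater"` or `"two.sided"`.
#' @param rule Membership rule, see [genes_in_regions()].
#' @return A `perm_test` list: `observed`, `null`, `p`, `alternative`,
#'   `n_perm`, `seed`, `scheme`.
#' @export
permutation_test_density <- function(genes, regions, contig_lengths,
                                     n_perm = 1000, seed = NULL,
                                     alternative = c("less", "greater",
                                                     "two.sided"),
                                     rule = "midpoint") {
  alternative <- match.arg(alternative)
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  if (nrow(regions) == 0) stop("region set is empty", call. = FALSE)
  observed <- attr(genes_in_regions(genes, regions, rule = rule,
                                    contigs = names(contig_lengths)),
                   "count")
  lookup <- region_lookup(regions, contig_lengths)
  lens <- as.numeric(contig_lengths)

  null <- with_seed(seed, {
    counts <- matrix(0L, nrow = n_perm, ncol = 0)
    totals <- numeric(n_perm)
    # genes of equal length share a placement distribution; group them
    for (gl in unique(genes$end - genes$start)) {
      n_g <- sum(genes$end - genes$start == gl)
      slots <- pmax(lens - gl + 1, 0)
      if (sum(slots) == 0) {
        stop("no contig can hold a gene of length ", gl, call. = FALSE)
      }
      m <- n_perm * n_g
      ctg_idx <- sample.int(length(lens), m, replace = TRUE,
                            prob = slots)
      start <- floor(stats::runif(m) * slots[ctg_idx])
      mid <- start + floor(gl / 2)
      memb <- lookup$member(ctg_idx, mid)
      totals <- totals + rowSums(matrix(memb, nrow = n_perm))
    }
    totals
  })
  structure(list(observed = observed, null = null,
                 p = perm_p_value(observed, null, alternative),
                 alternative = alternative, n_perm = as.integer(n_perm),
                 seed = seed, scheme = "uniform gene re-placement"),
            class = "perm_test")
}

#' Permutation test for duplicated-gene enrichment within CNV genes
#'
#' Holds the CNV membership of every gene fixed and permutes the
#' duplication-derived labels across all genes; the statistic is the
#' number of duplicated genes among CNV genes.  The default alternative
#' `"greater"` asks whether CNV genes are enriched for duplicates.
#'
#' @param duplicated_flags Logical vector, one per gene.
#' @param cnv_member Logical CNV-membership vector, one per gene.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @return A `perm_test` list.
#' @export
permutation_test_dup_enrichment <- function(duplicated_flags, cnv_member,
                                            n_perm = 1000, seed = NULL,
                                            alternative = c("greater",
                                                            "less",
                                                            "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(duplicated_flags) == length(cnv_member))
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  if (!any(cnv_member)) stop("no CNV genes", call. = FALSE)
  n <- length(duplicated_flags)
  observed <- sum(duplicated_flags & cnv_member)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      sum(duplicated_flags[sample.int(n)] & cnv_member)
    }, numeric(1))
  })
  structure(list(observed = observed, null = null,
                 p = perm_p_value(observed, null, alternative),
                 alternative = alternative, n_perm = as.integer(n_perm),
                 seed = seed, scheme = "duplication-label permutation"),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(paste0("<perm_test> observed = %g, null mean = %.2f, ",
                     "p = %.4g (%s, %d permutations, %s)\n"),
              x$observed, mean(x$null), x$p, x$alternative, x$n_perm,
              x$scheme))
  invisible(x)
}
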