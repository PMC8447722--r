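#' Parse RepeatMasker .out annotations
#'
#' Reads the standard RepeatMasker `.out` dialect (3 header lines, then
#' whitespace-separated hit lines with 1-based inclusive query
#' coordinates) into a 0-based half-open interval table.  Overlapping
#' hits are stored as-is; overlap handling is decided by the
#' contribution operations.
#'
#' @param file Path to a RepeatMasker `.out` file.
#' @return A `repeat_annotation` data.frame: `contig`, `start`, `end`,
#'   `family` (matching repeat), `repeat_class`.
#' @export
parse_repeatmasker <- function(file) {
  lines <- readLines(file)
  is_header <- grepl("^\\s*(SW|score|$)", lines)
  body_idx <- which(!is_header)
  rows <- lapply(body_idx, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 11) {
      stop("malformed RepeatMasker line ", i, ": ", lines[i],
           call. = FALSE)
    }
    qbegin <- suppressWarnings(as.numeric(f[6]))
    qend <- suppressWarnings(as.numeric(f[7]))
    if (is.na(qbegin) || is.na(qend) || qend < qbegin) {
      stop("malformed RepeatMasker line ", i, ": ", lines[i],
           call. = FALSE)
    }
    data.frame(contig = f[5], start = qbegin - 1, end = qend,
               family = f[10], repeat_class = f[11],
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) == 0) {
    data.frame(contig = character(0), start = numeric(0),
               end = numeric(0), family = character(0),
               repeat_class = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  class(out) <- c("repeat_annotation", "data.frame")
  out
}

#' Define a region set
#'
#' A labeled set of non-overlapping genomic intervals (0-based
#' half-open), e.g. the union of lowSD windows, all CNVs, or B-contigs.
#'
#' @param contig,start,end Interval columns.
#' @param label Region label.
#' @return A `region_set` data.frame with a `label` attribute and
#'   `total_bp` attribute.
#' @export
region_set <- function(contig, start, end, label = "region") {
  stopifnot(length(contig) == length(start), length(start) == length(end))
  if (any(end <= start)) stop("region intervals must have end > start",
                              call. = FALSE)
  out <- data.frame(contig = as.character(contig), start = start,
                    end = end, stringsAsFactors = FALSE)
  merged <- merge_intervals(out)
  if (sum(merged$end - merged$start) != sum(out$end - out$start)) {
    stop("region intervals must be non-overlapping", call. = FALSE)
  }
  attr(out, "label") <- label
  attr(out, "total_bp") <- sum(out$end - out$start)
  class(out) <- c("region_set", "data.frame")
  out
}

# union-merge a (contig, start, end) table via IRanges::reduce
merge_intervals <- function(df) {
  if (nrow(df) == 0) return(df[, c("contig", "start", "end")])
  pieces <- lapply(split(df, df$contig), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start + 1, d$end))
    data.frame(contig = d$contig[1], start = IRanges::start(ir) - 1,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# total bp of the union-merged intervals of `df` intersected with the
# union-merged intervals of `region`
intersect_bp <- function(df, region) {
  total <- 0
  for (ctg in intersect(unique(df$contig), unique(region$contig))) {
    a <- df[df$contig == ctg, ]
    b <- region[region$contig == ctg, ]
    ia <- IRanges::reduce(IRanges::IRanges(a$start + 1, a$end))
    ib <- IRanges::reduce(IRanges::IRanges(b$start + 1, b$end))
    total <- total + sum(IRanges::width(IRanges::intersect(ia, ib)))
  }
  total
}

#' Repeat-family contribution to a region
#'
#' Total bases of a repeat family's hits falling inside a region.
#' Overlapping hits of the same family are union-merged before length
#' summation, so the contribution measures covered sequence, not summed
#' hit lengths.
#'
#' @param annotation A `repeat_annotation`.
#' @param family Repeat family name.
#' @param region A `region_set`.
#' @return Contribution in bp (0 with a warning for unknown families).
#' @export
repeat_contribution <- function(annotation, family, region) {
  hits <- annotation[annotation$family == family, , drop = FALSE]
  if (nrow(hits) == 0) {
    warning("family ", family, " absent from annotation")
    return(0)
  }
  intersect_bp(hits, region)
}

#' Repeat enrichment index
#'
#' `E = (contribution in region / genome-wide contribution) /
#' (region bp / assembly bp)`.  `E > 1` means the repeat is enriched in
#' the region; when the region is the whole assembly, `E = 1` for every
#' family.
#'
#' @param contrib_in_region,contrib_genome Contributions in bp.
#' @param region_bp,assembly_bp Region and assembly sizes in bp.
#' @return Enrichment index (NA with a warning when the genome-wide
#'   contribution is zero).
#' @export
enrichment_index <- function(contrib_in_region, contrib_genome,
                             region_bp, assembly_bp) {
  stop_if_not_scalar_pos(region_bp, "region_bp")
  stop_if_not_scalar_pos(assembly_bp, "assembly_bp")
  if (any(contrib_genome == 0)) {
    warning("zero genome-wide contribution; enrichment undefined")
  }
  out <- (contrib_in_region / contrib_genome) / (region_bp / assembly_bp)
  out[contrib_genome == 0] <- NA_real_
  out
}

#' Per-family enrichment over one or more regions
#'
#' Convenience wrapper computing, for every family in the annotation,
#' its genome-wide contribution and enrichment index in each region.
#'
#' @param annotation A `repeat_annotation`.
#' @param regions A `region_set` or named list of them.
#' @param assembly_bp Assembly size in bp.
#' @return Data.frame: `family`, `region`, `contrib_bp`,
#'   `contrib_genome_bp`, `enrichment`.
#' @export
repeat_enrichment <- function(annotation, regions, assembly_bp) {
  if (inherits(regions, "region_set")) {
    regions <- stats::setNames(list(regions), attr(regions, "label"))
  }
  families <- sort(unique(annotation$family))
  out <- list()
  for (fam in families) {
    hits <- annotation[annotation$family == fam, , drop = FALSE]
    genome_bp <- sum(merge_intervals(hits)$end -
                     merge_intervals(hits)$start)
    for (rn in names(regions)) {
      reg <- regions[[rn]]
      in_bp <- intersect_bp(hits, reg)
      out[[length(out) + 1L]] <- data.frame(
        family = fam, region = rn, contrib_bp = in_bp,
        contrib_genome_bp = genome_bp,
        enrichment = enrichment_index(in_bp, genome_bp,
                                      attr(reg, "total_bp"), assembly_bp),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Top-contributing repeat families
#'
#' Families ranked by their union-merged genome-wide contribution
#' (descending, ties broken alphabetically), with their fraction of the
#' assembly.
#'
#' @param annotation A `repeat_annotation`.
#' @param assembly_bp Assembly size in bp.
#' @param n Number of families to report (default 36).
#' @return Data.frame: `rank`, `family`, `bp`, `fraction`.
#' @export
top_contributors <- function(annotation, assembly_bp, n = 36) {
  stop_if_not_scalar_pos(assembly_bp, "assembly_bp")
  fams <- unique(annotation$family)
  bp <- vapply(fams, function(fam) {
    m <- merge_intervals(annotation[annotation$family == fam, ,
                                    drop = FALSE])
    sum(m$end - m$start)
  }, numeric(1))
  ord <- order(-bp, fams)
  k <- min(n, length(fams))
  data.frame(rank = seq_len(k), family = fams[ord][seq_len(k)],
             bp = unname(bp[ord][seq_len(k)]),
             fraction = unname(bp[ord][seq_len(k)]) / assembly_bp,
             stringsAsFactors = FALSE)
}

#' Merge same-class windows into a region set
#'
#' Collapses the windows of one variability class (or any logical
#' selection of windows) into maximal intervals, yielding the region
#' sets used for repeat enrichment.
#'
#' @param window_set A `window_set`.
#' @param select Logical vector over windows (e.g. `classes ==
#'   "highSD"`).
#' @param label Region label.
#' @return A `region_set`.
#' @export
windows_to_regions <- function(window_set, select, label = "region") {
  stopifnot(length(select) == nrow(window_set))
  w <- window_set[select, , drop = FALSE]
  if (nrow(w) == 0) {
    return(region_set(character(0), numeric(0), numeric(0), label))
  }
  m <- merge_intervals(w)
  region_set(m$contig, m$start, m$end, label)
}
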