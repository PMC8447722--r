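#' Write a coverage matrix to TSV
#'
#' Columns: `window_id`, `contig`, `start`, `end` (0-based half-open),
#' then one coverage column per library.
#'
#' @param matrix A `cov_matrix`.
#' @param file Output path.
#' @export
write_coverage_tsv <- function(matrix, file) {
  stopifnot(inherits(matrix, "cov_matrix"))
  df <- cbind(data.frame(window_id = matrix$windows$index,
                         contig = matrix$windows$contig,
                         start = matrix$windows$start,
                         end = matrix$windows$end,
                         stringsAsFactors = FALSE),
              as.data.frame(matrix$values))
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read a coverage matrix from TSV
#'
#' @param file Path written by [write_coverage_tsv()] (or an external
#'   `samtools bedcov`-style step with the same layout).
#' @param normalized Is the stored matrix already exon-normalized?
#' @return A `cov_matrix`.
#' @export
read_coverage_tsv <- function(file, normalized = FALSE) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("window_id", "contig", "start", "end")
  stopifnot(all(meta_cols %in% names(df)))
  ws <- data.frame(contig = df$contig, start = df$start, end = df$end,
                   index = df$window_id, stringsAsFactors = FALSE)
  class(ws) <- c("window_set", "data.frame")
  vals <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  coverage_matrix(ws, vals, normalized = normalized)
}

#' Write a window set as BED
#'
#' @param window_set A `window_set`.
#' @param file Output path.
#' @param name Optional per-window name field (e.g. variability class).
#' @param score Optional numeric score field (e.g. window SD).
#' @export
write_windows_bed <- function(window_set, file, name = NULL,
                              score = NULL) {
  df <- data.frame(chrom = window_set$contig, start = window_set$start,
                   end = window_set$end, stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- name
  if (!is.null(score)) {
    if (is.null(name)) df$name <- "."
    df$score <- score
  }
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Write CNV regions as BED plus per-library coverage CSV
#'
#' @param cnvs A `cnv_regions` data.frame.
#' @param bed_file BED output path (name = CNV id, score = mean SD).
#' @param coverage_csv Optional path for the per-library mean coverage
#'   companion table.
#' @export
write_cnv_bed <- function(cnvs, bed_file, coverage_csv = NULL) {
  df <- data.frame(chrom = cnvs$contig, start = cnvs$start,
                   end = cnvs$end, name = cnvs$cnv_id,
                   score = round(cnvs$mean_sd, 4),
                   stringsAsFactors = FALSE)
  utils::write.table(df, bed_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(coverage_csv)) {
    cov <- attr(cnvs, "lib_coverage")
    utils::write.csv(data.frame(cnv_id = rownames(cov), cov,
                                check.names = FALSE), coverage_csv,
                     row.names = FALSE)
  }
  invisible(bed_file)
}

#' Write every simulator output for one population
#'
#' One call materializing the full synthetic data bundle: windows BED,
#' raw coverage TSV, library metadata TSV, genotypes CSV, per-library
#' GC TSV and a ddPCR CSV for one CNV locus across clones.
#'
#' @param dir Output directory (created if needed).
#' @param config A [sim_config()].
#' @param seed Seed for all draws.
#' @param n_reads Reads per library for the GC sample.
#' @param locus_element Element id measured by the emulated ddPCR assay
#'   (default: first element).
#' @return Invisibly, the list of generated objects.
#' @export
write_sim_outputs <- function(dir, config = sim_config(), seed = 1,
                              n_reads = 10000, locus_element = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pop <- simulate_population(config, seed = seed)
  libs <- simulate_libraries(pop, config, seed = seed + 1)
  cov <- simulate_coverage_matrix(pop, libs, config, seed = seed + 2)

  write_windows_bed(config$window_set, file.path(dir, "windows.bed"))
  write_coverage_tsv(cov$matrix, file.path(dir, "coverage_raw.tsv"))
  utils::write.table(libs, file.path(dir, "library_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(as.data.frame(pop), file.path(dir, "genotypes.csv"),
                   row.names = FALSE)

  gc <- lapply(seq_len(nrow(libs)), function(i) {
    g <- pop[pop$clone_id == libs$clone_id[i], ]
    as.numeric(simulate_gc_reads(g, config, n_reads, seed = seed + 2 + i))
  })
  gc_df <- as.data.frame(stats::setNames(gc, libs$library_id),
                         check.names = FALSE)
  utils::write.table(gc_df, file.path(dir, "gc_values.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  if (is.null(locus_element)) locus_element <- config$elements[[1]]$id
  dd <- do.call(rbind, lapply(seq_len(nrow(pop)), function(i) {
    r <- simulate_ddpcr(pop[[locus_element]][i], seed = seed + 100 + i)
    est <- ddpcr_cn_from_readout(r)
    data.frame(locus = locus_element, clone_id = pop$clone_id[i],
               true_cn = pop[[locus_element]][i],
               T = r$conc[r$channel == "T"],
               R1 = r$conc[r$channel == "R1"],
               R2 = r$conc[r$channel == "R2"],
               cn_estimate = est$cn, cn_lo = est$ci[1], cn_hi = est$ci[2],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(dd, file.path(dir, "ddpcr.csv"), row.names = FALSE)

  invisible(list(population = pop, libraries = libs, coverage = cov,
                 ddpcr = dd))
}
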