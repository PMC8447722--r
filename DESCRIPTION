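Package: popcnv
Title: Copy Number Variation and Genome Size Analysis from Window Coverage
    in Clonal Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects large copy-number-variable regions (CNVs) from
    cross-library window depth-of-coverage, classifies genomic windows by
    coverage variability, flags contigs that behave like B-chromosomes,
    decomposes per-read GC-content into Gaussian mixture fractions,
    quantifies repeat enrichment and gene depletion inside CNVs, and
    estimates locus copy numbers from droplet digital PCR readouts.  A
    bundled population simulator generates clone genotypes carrying 0-6
    copies of independently segregating megabase-scale genomic elements,
    window coverage matrices, per-read GC samples and ddPCR droplet counts
    with the statistical structure the analysis assumes, so the whole
    pipeline can be exercised and validated without any sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
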