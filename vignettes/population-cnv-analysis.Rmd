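---
title: "Detecting copy-number-variable regions and genome size variation in clonal populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting copy-number-variable regions and genome size variation in clonal populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popcnv)
```

## The problem

Some eukaryote populations harbor striking within-population genome size
variation carried by large, independently segregating genomic elements
(ISEs): megabase-scale blocks of mostly satellite DNA present in 0-6
copies per individual. In clonal rotifer populations this produces up to
near-twofold 2C genome size differences among clones of a single lake
population. `popcnv` implements the read-coverage side of that analysis:
given short-read libraries from many clones aligned to one reference
assembly, it locates the genomic regions whose copy number varies across
the population, characterizes their repeat and gene content, decomposes
the GC signature the elements leave in raw reads, and estimates exact
locus copy numbers from droplet digital PCR.

Because the real data require a full alignment pipeline, the package
ships a population simulator that generates every input the analysis
consumes — genotypes, window coverage matrices, per-read GC values and
ddPCR droplet readouts — with the statistical structure the method
assumes. All tests run against this simulator.

## Coverage model and normalization

The unit of analysis is a fixed-size window (5 kb for CNV detection,
50 kb for genome-wide overviews; 0-based half-open coordinates
throughout, the BED convention). For each library, the mean per-base
depth of coverage per window is divided by **half the library's mean
exon coverage**. Exons behave as single-copy diploid sequence, so a
diploid window scores 2 after normalization and a window inside an
element carried in $c$ copies scores $c$:

$$\mathrm{cov}_{norm} = \frac{\mathrm{cov}_{raw}}{\tfrac12\,
\mathrm{cov}_{exon}}$$

We compute the mean exon coverage as total aligned bases over exonic
positions divided by total exonic bases (length-weighted, robust to tiny
exons). Normalization is scale-equivariant: rescaling a library's raw
coverage and its exon mean by the same factor leaves the result
unchanged.

Cross-library variability per window is the sample standard deviation
(n − 1 denominator) of normalized coverage over **all libraries** (not
collapsed to clones — technical replicates carry real prep-level
information). Windows are classified as `lowSD` (sd ≤ 0.7; the diploid
background, whose variability peaks near 0.15), `interSD`
(0.7 < sd ≤ 2.0) and `highSD` (sd > 2.0). Boundary values go to the
lower class; the thresholds as published use strict inequalities that
leave boundary points unassigned, so a tie-break had to be fixed.

## The CNV caller

`detect_cnvs()` merges adjacent 5-kb windows into CNV regions by five
rules applied per contig:

1. a window is a CNV **seed** iff its cross-library SD exceeds 0.7;
2. two adjacent seed windows belong to one CNV iff their per-library
   coverage vectors are significantly correlated at $p < 0.05$;
3. the very first and last window of a contig, which often show deviant
   coverage at assembly edges, are merged into a neighboring CNV run
   when one exists (they never seed a CNV on their own);
4. two CNV runs separated by exactly one window (a "breakpoint") are
   merged iff the two windows flanking the gap are significantly
   correlated — iterated until no further merge applies;
5. only runs of at least three adjacent windows are reported.

The correlation in rules 2 and 4 is a partial Pearson correlation with
the library prep batch partialled out (plain Pearson via
`correlation = "pearson"`). The prep batch is the one covariate the
coverage data are demonstrably confounded by: some preps inflate
coverage specifically at high-GC CNV regions. p-values come from the
t-transform of r with $df = n_{lib} - 2 - q$, where $q$ is the number of
batch dummy columns; no multiple-testing correction is applied by
default (a Benjamini-Hochberg switch exists). The minimum-length filter
runs **after** bridging, and bridging absorbs the breakpoint window into
the merged region. Detection contains no randomness.

Design choices where the procedure was genuinely open:

* correlations use the 29 library vectors, not 15 clone means;
* a seed run is terminated when its neighbor fails the correlation
  test, even if a window further away would pass (gaps wider than one
  window are never bridged);
* an edge window adjacent to diploid sequence stays unassigned — the
  edge rule prevents spurious breakpoints at contig ends, it does not
  seed CNVs;
* terminal partial windows of a contig are kept (`drop_partial = FALSE`
  in `tile_windows()`), maximizing assembly coverage.

Contigs whose length is ≥ 90% covered by CNV regions are flagged as
**B-contigs** (`classify_b_contigs()`), in analogy to B-chromosomes; a
stricter 95% flag is reported alongside. `cnv_summary()` reports count,
total bp, assembly fraction and the N50 of the CNV length distribution.

## GC mixture decomposition

Reads from satellite-rich elements carry elevated GC. Pooled per-read
GC distributions are tri-modal and are modeled as a three-component
normal mixture; the reference generator uses components
$26 \pm 6$, $36 \pm 2.5$ and $48 \pm 3$ %GC. `fit_gc_mixture()` is a
standard univariate EM with:

* deterministic quantile initialization (means at the 1/6, 3/6, 5/6
  sample quantiles, pooled SD, equal weights);
* convergence at relative log-likelihood improvement below `tol = 1e-6`
  (`max_iter = 1000`); the log-likelihood trace is recorded and is
  non-decreasing by construction — tests assert it;
* component SDs floored at $10^{-6}$ to avoid singular collapse;
* reported components always sorted by ascending mean, so
  label-switching cannot scramble per-library comparisons.

The default workflow fits the pooled reads once and then re-estimates
**only the weights** per library with the component means/SDs held
fixed (`fixed_components = `), because per-library fraction comparisons
are only meaningful against a common set of components; a full
per-library refit is available. Fits are on raw per-read values, as the
reference implementation of mixture EM operates on raw vectors.

In the simulator, mixture weights derive from the genotype: the low-GC
component mass is proportional to basal genome content, and each
element's content joins the component nearest its GC. Even element-free
clones keep floors of 10% (mid) and 3% (high) of basal mass in the
GC-elevated components — the basal genome is not GC-homogeneous. The
floors are a modeling choice fixed once; they reproduce the qualitative
pattern that the low-GC fraction falls, and the elevated fractions
rise, with genome size.

## Repeat enrichment and gene statistics

Repeat annotations are read from RepeatMasker `.out` files (1-based
inclusive, converted to 0-based half-open). A family's contribution to
a region is the **union-merged** covered length intersected with the
region — overlapping hits of one family count once; "total length
covered" is coverage, not summed hit lengths. Cross-family overlaps are
counted once per family, giving per-family marginal contributions. The
enrichment index of family $f$ in region $R$ is

$$E = \frac{\mathrm{contrib}_f(R) / \mathrm{contrib}_f(G)}
{|R| / |G|},$$

with $E > 1$ meaning enrichment. Two identities pin the implementation
down and are tested to $10^{-9}$: $E = 1$ when $R$ is the whole
assembly, and the region-size-weighted mean of $E$ over any partition
of the assembly is 1.

Gene depletion in CNVs and the excess of duplication-derived genes
among CNV genes are tested by Monte Carlo permutation (1000
permutations by default, plus-one-corrected empirical p-values that can
never be zero). The published analysis does not state its permutation
scheme, so the two minimal schemes consistent with in/out comparisons
are implemented and flagged in every result object:

* **density test** — each gene is re-placed uniformly at random,
  preserving its length, within a contig chosen with probability
  proportional to its number of valid start positions; the statistic is
  the count of genes whose midpoint lies in the region set;
* **duplication test** — duplication labels are permuted across all
  genes with CNV membership held fixed; the statistic is the number of
  duplicated genes among CNV genes (its permutation null is exactly
  hypergeometric, which a test exploits as an independent oracle).

Membership uses the gene midpoint by default (`rule = "overlap"` with a
fraction cutoff as alternative). Because the count statistic is
integer-valued, the plus-one-corrected p-value is conservative on
discrete ties; with several hundred genes the discreteness is small
enough that type-I error stays near nominal, which the acceptance test
checks against the [0.035, 0.065] band at α = 0.05.

## ddPCR copy numbers and coverage utilities

Locus copy number from droplet digital PCR concentrations:

$$CN = \frac{T}{(R_1 + R_2)/2}\, N_R,$$

with target concentration $T$, two diploid reference amplicons $R_1,
R_2$ and $N_R = 2$. Concentration CIs are propagated conservatively as
the range of the ratio over the CI box
($[T_{lo}/\bar R_{hi},\; T_{hi}/\bar R_{lo}] \cdot N_R$); no
propagation formula is published for the ratio, so the conservative
interval was chosen — it over-covers (the simulator round-trip shows
well above 93% coverage of the true integer copy number at 15,000
droplets). Estimates are not rounded to integers.

The ddPCR simulator uses standard Poisson partitioning: droplet
negative probability $e^{-\lambda}$, concentration
$-\ln(p_{neg})/V_{droplet}$ with a 0.85 nl droplet volume and a
loading of 0.8 molecules/droplet for a diploid locus; channel CIs come
from the delta-method SE of $-\ln p$.

Two closed-form utilities: kmer-to-base coverage conversion
$C = C_K R / (R - K + 1)$ and the naive coverage estimate
total bp / 1C genome size.

## What the simulator does and does not emulate

Defaults fix the study conditions once: 15 clones (clone 1 forced to
the basal all-zero genotype), 29 libraries in the published 1-4
libraries-per-clone pattern, six prep batches A-F, basal 2C of 414 Mb,
and three elements — 34 Mb/copy at GC 36% (200 windows, one whole
contig), 17 Mb/copy at GC 48% (100 windows, one whole contig), and
0.51 Mb/copy at GC 36% (3 windows, internal to a core contig). Element
window footprints are proportional to element size, so per-library CNV
coverage and 2C genome size stay on one scale. Copy numbers are
zero-inflated binomial (zero with probability 0.25, else
Binomial(6, 0.4)), spanning the observed 0-6 range with a realistic
share of zero-copy clones. Coverage noise is multiplicative Gamma with
mean 1 and CV 0.1 (read depth is overdispersed, strictly positive and
roughly multiplicative); per-batch GC bias is a lognormal multiplier
(sdlog 0.08) applied to windows above 32% GC. Crosses transmit each
parental element copy independently with probability 1/2 — the
simplest model that makes elements segregate independently and
offspring means midparent.

The toy assembly is ~4.75 Mb against the real 230 Mb: window counts,
not genome scale, drive the statistics being tested. Not emulated:
nucleotide-level reads and alignment (coverage is simulated at window
resolution), mapping artifacts near repeats, reference bias from an
unphased assembly carrying multiple element copies, and
GC-bias-fragmentation chemistry beyond a single per-batch multiplier.
Passing tests therefore validate the algorithmic pipeline under its own
model assumptions, not the upstream alignment steps.

## Problem sizes used in the test suite

The bundled checks run at desk scale: coverage matrices of ~950 windows
by 29 libraries, EM fits at 100,000 reads over 20 seeds, 40 brute-force
detector fixtures of up to 50 windows, 1000 permutation-null replicates
of 400 genes with 199 permutations each, and 1000 ddPCR round-trip
replicates at 15,000 droplets. These sizes give tight Monte Carlo error
on every assertion while the whole suite completes in a few minutes.

## Known limitations

* Quantitative genome size prediction from coverage alone is not
  attempted: prep-batch GC bias inflates CNV coverage differentially,
  which is exactly why exact copy numbers go through ddPCR.
* The detector's correlation tests assume enough libraries for a
  t-based p-value after partialling out batch; with very few libraries
  use `correlation = "pearson"`.
* Windows smaller than the 5-kb resolution and sub-window indels are
  invisible by construction.
* The EM fits a fixed k = 3; model selection over k is out of scope.
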