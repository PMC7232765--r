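---
title: "Methods: partitioning genetic and epigenetic population divergence"
author: "epiDiverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioning genetic and epigenetic population divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiDiverge)
```

## The scientific question

Populations facing heterogeneous environments can diverge genetically
(allele-frequency differences accumulating under drift and selection) or
epigenetically (persistent, environmentally responsive marks such as CpG
methylation). epiDiverge implements a desk-scale pipeline for asking which
mode dominates in a multi-population sample assayed with
reduced-representation sequencing: RAD-style SNP genotypes on one side and
RRBS/epiGBS-style CpG methylation counts on the other. The motivating system
is the Eastern oyster (*Crassostrea virginica*) sampled from four Gulf of
Mexico estuaries with very different salinity regimes, but every component is
generic.

The pipeline's two headline statistics are:

* **F_ST** — per-locus Weir & Cockerham (1984) theta, estimated from the
  variance components *a* (among populations), *b* (among individuals within
  populations) and *c* (within individuals):
  `theta = a / (a + b + c)`.
* **P_ST** — a methylation analogue of F_ST computed per region from
  per-individual methylation fractions:
  `P_ST = (Var_Total - Var_Sub) / Var_Total`, where `Var_Total` is the
  sample variance across all individuals pooled and `Var_Sub` is the
  unweighted mean of the per-population sample variances.

Comparing mean P_ST to mean F_ST measures whether divergence in the
methylome exceeds divergence in allele frequencies.

## Estimators and their assumptions

### Weir--Cockerham theta

`wcTheta()` / `perLocusFst()` implement the WC84 estimator for biallelic
loci from per-population sample sizes, allele frequencies and observed
heterozygosities. Missing genotypes reduce the per-locus, per-population
sample size; a population with no calls at a locus drops out of that locus's
sums; loci with fewer than two scored populations, or a zero total variance
(global monomorphism), return an undefined theta that is excluded from (and
counted alongside) summaries. No Hardy--Weinberg assumption is imposed:
observed heterozygosity enters the components directly. "Mean F_ST" is
ambiguous between the arithmetic mean of per-locus thetas and the ratio of
summed components, so `meanFst()` returns both; the arithmetic mean is the
headline value. Gene-level F_ST (`geneFst()`) pools `sum(a)/sum(a+b+c)` over
the loci of a gene body, which weights each locus by its total-variance
denominator — the natural weighting when the per-gene quantity should behave
like a ratio-of-sums estimate; the per-locus table is emitted so other
weightings can be applied.

Upstream of estimation, `filterLoci()` applies the RAD-style rules: a locus
must be genotyped in at least 65% of individuals in at least 2 populations,
have an overall minor-allele frequency of at least 0.05, and contribute only
its first SNP per RAD locus. All three thresholds are arguments.

### Tiled differential methylation

Coverage parsing (`readBismarkCoverage()`) accepts both the 0-based and
1-based dialects of the 6-column bismark coverage format and recomputes
fractions from counts (the percent column is ignored). `filterByCoverage()`
drops CpGs with fewer than 10 reads (inclusive boundary: exactly 10 is
kept). `makeTiles()` pools counts into non-overlapping 100-bp windows
anchored at coordinate 0 of each chromosome — tile width equals step, so
each CpG lands in exactly one tile and counts are conserved. A tile is
retained only when at least 8 individuals per group have at least one read
in it; "covered" means one read after the per-CpG depth filter, the
weakest defensible reading, documented because stricter definitions are
easily imposed by raising `min_reads`.

`dmrTest()` tests each tile with a binomial logistic likelihood-ratio test
of the group term on per-individual (methylated, total) counts. With a
single two-level factor, the group-wise MLEs are the pooled count fractions,
so the LRT is evaluated in closed form (it equals the
`glm(cbind(meth, unmeth) ~ group, binomial)` deviance test, which the test
suite verifies). No overdispersion correction is applied — this mirrors the
default behaviour of standard tile-testing tools; the practical error
control comes from the compound DMR definition below. Groups reduced to a
single covered sample fall back to an exact 2x2 test on pooled counts.
P-values are Benjamini--Hochberg adjusted within each pairwise comparison
(the family is one comparison's tiles). A tile is a DMR only when both
`|meth_diff| >= 15` percentage points and `q <= 0.05`; `meth_diff` is the
difference of coverage-pooled group percentages (matching the pooled-count
test statistic), not the mean of per-individual fractions, and is oriented
focal group minus other so hyper/hypo calls are unambiguous. Under a null
simulation with individual-level biological noise, the 15-point requirement
keeps the realized DMR rate near zero even though pooled-count p-values are
anticonservative under overdispersion; the acceptance suite measures this
directly.

`clusterAndProject()` restricts to tiles covered in every sample, computes
fraction vectors, and applies Ward clustering (`hclust`, `"ward.D"`) on
1 − Pearson correlation distances plus a PCA of the centered fraction
matrix. Constant sample vectors make the correlation undefined and raise an
error naming the sample.

### P_ST

`pstRegion()`/`pstTiles()` compute the variance partition per region.
Decisions taken where the definition is open:

* `Var_Sub` is the **unweighted mean** of per-population sample variances,
  so one P_ST exists per region regardless of the number of populations;
  per-population variances are emitted alongside so a focal-population
  variant can be formed by the user.
* Negative P_ST values (sampling noise making `Var_Sub > Var_Total`) are
  **retained**, not clipped, so means stay unbiased around zero under the
  null.
* Regions with `Var_Total = 0` are undefined, excluded from means, and
  counted.
* Variances use the n−1 denominator and a numerically stable two-pass
  (explicit deviations) computation; the test suite requires 1e-12
  agreement (absolute, since the statistic is a difference ratio) with a
  direct-summation oracle.
* P_ST is computed at tile level by default (the mean over tiles is the
  headline value) and again after gene aggregation; both are reported
  because the region set behind a published "per locus" P_ST mean can be
  read either way.

P_ST is invariant under common affine rescaling of all fractions, which the
property suite checks; it carries no heritability-style scaling (no c/h²
adjustment) — it is a descriptive variance partition, not a quantitative-
genetics estimate.

### Feature annotation

`buildFeatureModel()` derives promoter / 5'UTR / exon / intron / 3'UTR /
downstream annotation from GFF3: introns are the gene span minus exon
cover; promoters and downstream regions are strand-aware 2-kb flanks
clipped at chromosome bounds (symmetric by design: both flank types can
regulate expression); the first transcript per gene is used. Tiles classify
by maximal base-pair overlap with ties broken by the precedence
5'UTR > 3'UTR > exon > intron > promoter > downstream — UTRs sit inside
exons, so only the tie rule lets them win, and smaller, more specific
features outrank larger ones. Tiles with zero gene-linked overlap are
intergenic, annotated with the nearest gene by midpoint distance.

`generateRandomTiles()` draws uniform random tile sets (chromosomes weighted
by valid start positions; overlaps allowed; optional BED-style mask for real
genomes). `compareFeatureDistributions()` applies a two-sample KS test to
the two category distributions *as distributions over the ordered category
axis*: `D = max |cumsum(observed) − cumsum(reference)|`, with the p-value
from expanding each distribution back to its tile-count sample. Treating
seven fractions as seven raw observations would make identically supported
distributions incomparable; the CDF-over-categories reading is the one
under which "identical distributions give D = 0" and "completely disjoint
distributions give D = 1" both hold. It remains an interpretation — category
order matters — so the per-set fractions are exported for alternative nulls.

### Salinity profiling

Daily salinities bin into five regimes tied to oyster tolerance:
`[0, 3.5)`, `[3.5, 6)`, `[6, 15)`, `[15, 20)` and `[20, Inf)` psu.
Boundaries are upper-exclusive except the top bin, which is
lower-inclusive, reconciling "15–20" with ">20" labels; a day at exactly
20 psu counts as ">20", and the convention is documented because the
opposite choice is equally defensible. Same-day duplicates are averaged to
daily values first. `windowMean()` averages the available values in the 10
days strictly before a collection date, reporting the missing-day count.

## The synthetic-data generators

The generators exist so every estimator can be validated against known
truth; their defaults encode the emulated study design.

* **Genotypes** (`simulateGenotypes()`): Balding--Nichols — ancestral
  frequency `p ~ Uniform(0.1, 0.9)`, per-population frequency
  `Beta(p(1−F)/F, (1−p)(1−F)/F)`, diploid dosages `Binomial(2, p_pop)`.
  Balding--Nichols was chosen because its single parameter equals the
  expected theta, making calibration transparent. The default
  `F = 1/(1 + 4·Nm)` with `Nm = 10.625` corresponds to island-model
  equilibrium at the divergence the study design implies (F ≈ 0.023).
  Defaults: 4 populations, 20 (genotypes: set to 22 in the calibration
  runs, matching the RAD design) diploids per population, 1,567 loci, no
  missingness (the calibration design states none; `missing_rate` raises
  it for robustness tests). Loci are unlinked; F = 0 and F = 1 are rejected
  (degenerate Beta).
* **Methylomes** (`simulateMethylomes()` / `simulateTileFractions()`):
  per tile a base mean `Uniform(0.3, 0.7)` — kept away from the boundaries
  so that truncation to [0,1] is negligible and the variance algebra stays
  exact — population offsets `Normal(0, 0.0383)`, individual fractions
  `Normal(pop mean, 0.10)` truncated to [0,1] (a warning fires if any tile
  truncates more than 10% of its mass). Gaussian-on-fraction rather than
  Beta noise keeps the P_ST expectation analytic: with n individuals in
  each of k populations (N = nk total),
  `E[Var_Total] ≈ sigma_w² + sigma_b²·n(k−1)/(N−1)`, so
  `sigma_b = 0.0383` with `sigma_w = 0.10`, n = 20, k = 4 puts the design
  P_ST at 0.10. Read counts are `Poisson(mean_read_depth = 30)` per CpG
  (3 CpGs per 100-bp tile) with `Binomial(depth, fraction)` methylated
  reads; Poisson rather than negative-binomial by default because depth
  overdispersion is irrelevant to the fraction-scale statistics validated
  here.
* **Annotation** (`simulateGenomeAnnotation()`): non-overlapping genes with
  5'UTR, 1–3 exons, introns and 3'UTR on alternating strands along a 1-Mb
  chromosome, 100 genes by default, randomized intergenic gaps; infeasible
  packing is rejected.
* **Salinity** (`simulateSalinitySeries()`): site mean plus Gaussian daily
  noise, floored at 0 psu.

All generators are deterministic: a fixed seed yields byte-identical files,
and every emitted file parses through the pipeline's own readers.

What the generators deliberately do **not** emulate: genome-scale CpG
density (real RRBS yields millions of cytosines; tiles here are dense and
contiguous), linkage between SNP loci, bisulfite-conversion error,
read-level artifacts, and spatial autocorrelation of methylation along
chromosomes. Consequently, passing tests demonstrate the correctness and
calibration of the estimators under the declared sampling model — not that
real oyster data would reproduce any particular value.

## Numerical and degenerate-input choices

* Internal coordinates are Bioconductor-native 1-based `GRanges`;
  converters sit at every format boundary (0-based coverage dialect, GFF3,
  and tile TSVs printed with 0-based half-open starts to match the
  coverage convention).
* The binomial log-likelihood uses the `0·log 0 = 0` convention; the LRT is
  floored at zero before the chi-square tail call.
* Group variances use two-pass deviations; tiny negative variances cannot
  arise.
* Ties in feature classification break by the fixed precedence; ties in
  Ward clustering follow `hclust`'s defaults.
* Undefined quantities (theta with zero denominator, P_ST with zero total
  variance, correlations of constant columns) are NA and flagged, never
  silently dropped to zero.
* Errors carry package-specific condition classes
  (`epiDiverge_config_error`, `epiDiverge_parse_error`, ...) so the
  pipeline driver and callers can handle them by name.

## Problem sizes

The validation suite runs at the scale the analysis emulates where that is
cheap (1,567 loci x 88 individuals x 20 replicate seeds for F_ST recovery;
5,000 tiles x 80 individuals for P_ST recovery; 2,000 tiles for null
error-rate checks; 1,000 random instances per estimator-oracle comparison)
and at deliberately small scale for end-to-end pipeline runs (a 60-kb
genome with 25 genes, 120 tiles and 300 loci), chosen so the full suite
completes in about a minute and a half while still exercising every stage
against known truth.

## Known limitations

* The binomial LRT ignores individual-level overdispersion; its raw
  p-values are anticonservative when within-group biological variance is
  large. The compound DMR rule (effect-size plus q-value) is what controls
  the realized false-positive rate, and the acceptance suite verifies this
  empirically rather than assuming it.
* The KS comparison of feature distributions depends on the category
  ordering, as discussed above.
* Gene-level aggregation uses the first transcript per gene; isoform-level
  annotation is out of scope.
* P_ST has no heritability interpretation; it is a descriptive variance
  ratio on filtered coverage data.
* Pairwise F_ST matrices beyond the multi-population theta (and its
  restriction to two groups via the grouping argument) are not produced;
  population-structure inference is consumed as an input column
  (`meta_population`), never estimated.
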