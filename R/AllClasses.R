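#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width
#'   strand mcols mcols<- findOverlaps pintersect reduce
#' @importFrom IRanges IRanges subsetByOverlaps
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels keepSeqlevels
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowRanges colData colData<-
#' @importFrom stats rbinom rbeta rpois rnorm runif var cor prcomp hclust
#'   as.dist p.adjust pchisq fisher.test ks.test setNames complete.cases
#' @importFrom utils read.table write.table
NULL

## ---------------------------------------------------------------------------
## SimConfig: study-design parameters for the synthetic-data generators
## ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Holds the study-design parameters shared by the synthetic-data generators:
#' a Balding--Nichols genotype model for a set of diverging populations, a
#' hierarchical (between-population / within-population) model of CpG
#' methylation fractions over 100-bp tiles, a simple gene-model layout, and a
#' common genome coordinate system. Defaults emulate a four-population oyster
#' study: 4 populations, 20 diploids each, 1,567 biallelic loci at expected
#' divergence F = 1/(1 + 4\*Nm) with Nm = 10.625, and 5,000 methylation tiles
#' with between-population SD 0.0383 and within-population SD 0.10 on the
#' fraction scale.
#'
#' @slot n_populations number of populations.
#' @slot n_individuals_per_pop diploid individuals per population.
#' @slot n_loci biallelic SNP loci to simulate.
#' @slot divergence_F Balding--Nichols divergence parameter, equal to the
#'   expected Weir--Cockerham theta; must lie strictly in (0, 1).
#' @slot ancestral_freq_range range of the uniform ancestral allele frequency.
#' @slot missing_rate per-call probability that a genotype is masked missing.
#' @slot n_tiles number of 100-bp methylation tiles.
#' @slot sigma_between SD of population-level offsets of tile mean methylation
#'   (fraction scale).
#' @slot sigma_within SD of individual fractions around their population mean.
#' @slot base_mean_range range of the uniform per-tile base mean methylation.
#' @slot mean_read_depth Poisson mean read depth per CpG.
#' @slot cpgs_per_tile CpG sites per tile.
#' @slot genome_length length of the single simulated chromosome (bp).
#' @slot n_genes number of non-overlapping gene models to place.
#' @slot tile_size tile width in bp.
#' @slot seed integer seed; a fixed seed gives byte-identical outputs.
#'
#' @seealso [simConfig()] for the user constructor.
#' @export
setClass("SimConfig",
  slots = c(
    n_populations         = "integer",
    n_individuals_per_pop = "integer",
    n_loci                = "integer",
    divergence_F          = "numeric",
    ancestral_freq_range  = "numeric",
    missing_rate          = "numeric",
    n_tiles               = "integer",
    sigma_between         = "numeric",
    sigma_within          = "numeric",
    base_mean_range       = "numeric",
    mean_read_depth       = "numeric",
    cpgs_per_tile         = "integer",
    genome_length         = "numeric",
    n_genes               = "integer",
    tile_size             = "integer",
    seed                  = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  chkcount <- function(x, nm, min = 1L) {
    if (length(x) != 1L || is.na(x) || x < min)
      sprintf("'%s' must be a single count >= %d", nm, min) else character()
  }
  chkfrac <- function(x, nm) {
    if (any(is.na(x)) || any(x < 0) || any(x > 1))
      sprintf("'%s' must lie in [0, 1]", nm) else character()
  }
  msg <- c(msg,
    chkcount(object@n_populations, "n_populations", 1L),
    chkcount(object@n_individuals_per_pop, "n_individuals_per_pop"),
    chkcount(object@n_loci, "n_loci"),
    chkcount(object@n_tiles, "n_tiles"),
    chkcount(object@cpgs_per_tile, "cpgs_per_tile"),
    chkcount(object@n_genes, "n_genes", 0L),
    chkcount(object@tile_size, "tile_size"),
    chkfrac(object@missing_rate, "missing_rate"),
    chkfrac(object@ancestral_freq_range, "ancestral_freq_range"),
    chkfrac(object@base_mean_range, "base_mean_range"))
  if (object@divergence_F <= 0 || object@divergence_F >= 1)
    msg <- c(msg, "'divergence_F' must lie strictly in (0, 1): 0 and 1 make the Balding-Nichols Beta degenerate")
  if (length(object@ancestral_freq_range) != 2L ||
      diff(object@ancestral_freq_range) < 0)
    msg <- c(msg, "'ancestral_freq_range' must be an increasing pair")
  if (length(object@base_mean_range) != 2L || diff(object@base_mean_range) < 0)
    msg <- c(msg, "'base_mean_range' must be an increasing pair")
  if (object@sigma_between < 0 || object@sigma_within < 0)
    msg <- c(msg, "sigma values must be >= 0")
  if (object@mean_read_depth < 1)
    msg <- c(msg, "'mean_read_depth' must be >= 1")
  if (object@genome_length < object@n_tiles * object@tile_size)
    msg <- c(msg, "'genome_length' must cover n_tiles * tile_size")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' @param n_populations,n_individuals_per_pop,n_loci,divergence_F,ancestral_freq_range,missing_rate,n_tiles,sigma_between,sigma_within,base_mean_range,mean_read_depth,cpgs_per_tile,genome_length,n_genes,tile_size,seed
#'   see the slot documentation in [SimConfig-class].
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(n_loci = 200L, n_tiles = 50L, seed = 7L)
#' cfg
#' @export
simConfig <- function(n_populations = 4L,
                      n_individuals_per_pop = 20L,
                      n_loci = 1567L,
                      divergence_F = 1 / (1 + 4 * 10.625),
                      ancestral_freq_range = c(0.1, 0.9),
                      missing_rate = 0,
                      n_tiles = 5000L,
                      sigma_between = 0.0383,
                      sigma_within = 0.10,
                      base_mean_range = c(0.3, 0.7),
                      mean_read_depth = 30,
                      cpgs_per_tile = 3L,
                      genome_length = 1e6,
                      n_genes = 100L,
                      tile_size = 100L,
                      seed = 1L) {
  new("SimConfig",
      n_populations = as.integer(n_populations),
      n_individuals_per_pop = as.integer(n_individuals_per_pop),
      n_loci = as.integer(n_loci),
      divergence_F = as.numeric(divergence_F),
      ancestral_freq_range = as.numeric(ancestral_freq_range),
      missing_rate = as.numeric(missing_rate),
      n_tiles = as.integer(n_tiles),
      sigma_between = as.numeric(sigma_between),
      sigma_within = as.numeric(sigma_within),
      base_mean_range = as.numeric(base_mean_range),
      mean_read_depth = as.numeric(mean_read_depth),
      cpgs_per_tile = as.integer(cpgs_per_tile),
      genome_length = as.numeric(genome_length),
      n_genes = as.integer(n_genes),
      tile_size = as.integer(tile_size),
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:",
      object@n_populations, "populations x",
      object@n_individuals_per_pop, "individuals\n")
  cat("  genotypes:", object@n_loci, "loci, F =",
      signif(object@divergence_F, 4),
      ", missing rate", object@missing_rate, "\n")
  cat("  methylome:", object@n_tiles, "tiles x", object@cpgs_per_tile,
      "CpGs, sigma (between, within) = (",
      object@sigma_between, ",", object@sigma_within, ")\n")
  cat("  genome:", format(object@genome_length, big.mark = ","),
      "bp,", object@n_genes, "genes; seed", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## CpGCoverage: one individual's CpG read counts
## ---------------------------------------------------------------------------

#' Per-individual CpG coverage
#'
#' Read counts at CpG positions for a single individual, as parsed from a
#' bismark coverage file. Positions are stored 1-based in a [GRanges] with
#' metadata columns `meth` and `unmeth`.
#'
#' @slot individual sample identifier.
#' @slot sites a `GRanges` of width-1 CpG positions with integer metadata
#'   columns `meth` and `unmeth`.
#' @export
setClass("CpGCoverage",
  slots = c(individual = "character", sites = "GRanges"))

setValidity("CpGCoverage", function(object) {
  msg <- character()
  mc <- mcols(object@sites)
  if (!all(c("meth", "unmeth") %in% colnames(mc)))
    return("'sites' needs metadata columns 'meth' and 'unmeth'")
  if (length(object@sites)) {
    if (any(mc$meth < 0) || any(mc$unmeth < 0))
      msg <- c(msg, "read counts must be non-negative")
    key <- paste(seqnames(object@sites), start(object@sites))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate CpG positions within an individual")
  }
  if (length(object@individual) != 1L)
    msg <- c(msg, "'individual' must be a single id")
  if (length(msg)) msg else TRUE
})

#' @describeIn CpGCoverage-class number of CpG records.
#' @param x a `CpGCoverage`.
#' @export
setMethod("length", "CpGCoverage", function(x) length(x@sites))

setMethod("show", "CpGCoverage", function(object) {
  tot <- sum(mcols(object@sites)$meth + mcols(object@sites)$unmeth)
  cat("CpGCoverage for", object@individual, "-", length(object@sites),
      "CpGs,", tot, "reads\n")
})

#' Accessors for CpGCoverage
#'
#' `cpgSites()` returns the underlying `GRanges`; `individualId()` the sample
#' identifier.
#'
#' @param x a [CpGCoverage-class] object.
#' @return `cpgSites`: a `GRanges`; `individualId`: a character scalar.
#' @export
cpgSites <- function(x) {
  stopifnot(is(x, "CpGCoverage"))
  x@sites
}

#' @rdname cpgSites
#' @export
individualId <- function(x) {
  stopifnot(is(x, "CpGCoverage"))
  x@individual
}

## ---------------------------------------------------------------------------
## MethylTileSet: tiled methylation counts across samples
## ---------------------------------------------------------------------------

#' Tiled methylation counts
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] subclass holding, for
#' each 100-bp tile (rows) and individual (columns), the pooled methylated
#' read count (`meth` assay) and total read count (`total` assay). `colData`
#' carries the `individual` id and its `population` label (plus any
#' meta-population column supplied with the population map).
#'
#' @export
setClass("MethylTileSet", contains = "RangedSummarizedExperiment")

setValidity("MethylTileSet", function(object) {
  msg <- character()
  if (!all(c("meth", "total") %in% names(assays(object))))
    return("assays 'meth' and 'total' are required")
  m <- assay(object, "meth"); tt <- assay(object, "total")
  if (any(m < 0) || any(tt < 0)) msg <- c(msg, "counts must be non-negative")
  if (any(m > tt)) msg <- c(msg, "'meth' cannot exceed 'total'")
  if (!"population" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'population' column")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MethylTileSet", function(object) {
  cat("MethylTileSet:", nrow(object), "tiles x", ncol(object), "samples (",
      length(unique(colData(object)$population)), "populations )\n")
  if (nrow(object)) {
    w <- width(rowRanges(object))
    cat("  tile width:", paste(unique(w), collapse = ","), "bp\n")
  }
})

#' Methylation fractions and pooled group percentages
#'
#' `methFraction()` returns the per-tile, per-individual methylation fraction
#' (`meth / total`, `NA` where the tile is uncovered). `pooledPercent()`
#' returns, per tile, the coverage-pooled percent methylation of each level of
#' a grouping: `100 * sum(meth) / sum(total)` over the group's individuals.
#'
#' @param x a [MethylTileSet-class].
#' @param groups a factor (or name of a `colData` column) grouping the
#'   columns of `x`.
#' @return `methFraction`: a numeric matrix (tiles x samples);
#'   `pooledPercent`: a numeric matrix (tiles x groups).
#' @export
methFraction <- function(x) {
  stopifnot(is(x, "MethylTileSet"))
  m <- assay(x, "meth"); tt <- assay(x, "total")
  f <- m / tt
  f[tt == 0] <- NA_real_
  f
}

#' @rdname methFraction
#' @export
pooledPercent <- function(x, groups = "population") {
  stopifnot(is(x, "MethylTileSet"))
  groups <- resolveGrouping(x, groups)
  ind <- groupIndicator(groups)
  ms <- assay(x, "meth") %*% ind
  ts <- assay(x, "total") %*% ind
  out <- 100 * ms / ts
  out[ts == 0] <- NA_real_
  out
}

## ---------------------------------------------------------------------------
## FeatureModel: genomic feature annotation derived from GFF3
## ---------------------------------------------------------------------------

#' Genomic feature model
#'
#' Promoter / 5'UTR / exon / intron / 3'UTR / downstream annotation derived
#' from GFF3 gene models, with strand-aware 2-kb promoter and downstream
#' flanks clipped to chromosome bounds. Anything not covered by these
#' gene-linked categories is intergenic.
#'
#' @slot genes `GRanges` of gene spans with a `gene_id` metadata column.
#' @slot features named `GRangesList` with elements `promoter`,
#'   `five_prime_UTR`, `exon`, `intron`, `three_prime_UTR`, `downstream`;
#'   every range carries a `gene_id`.
#' @slot seqlens named numeric vector of chromosome lengths (bp).
#' @slot flank promoter/downstream flank size in bp (default 2000).
#' @export
setClass("FeatureModel",
  slots = c(genes = "GRanges", features = "GRangesList",
            seqlens = "numeric", flank = "integer"))

.FEATURE_CATEGORIES <- c("promoter", "five_prime_UTR", "exon", "intron",
                         "three_prime_UTR", "downstream", "intergenic")

## precedence used to break overlap ties during classification
.FEATURE_PRECEDENCE <- c("five_prime_UTR", "three_prime_UTR", "exon",
                         "intron", "promoter", "downstream")

setValidity("FeatureModel", function(object) {
  msg <- character()
  need <- setdiff(.FEATURE_CATEGORIES, "intergenic")
  if (!all(need %in% names(object@features)))
    msg <- c(msg, paste("features must contain:", paste(need, collapse = ", ")))
  if (is.null(names(object@seqlens)) || any(object@seqlens <= 0))
    msg <- c(msg, "'seqlens' must be a named positive vector")
  for (nm in intersect(need, names(object@features))) {
    gr <- object@features[[nm]]
    if (length(gr)) {
      ok <- as.character(seqnames(gr)) %in% names(object@seqlens)
      if (!all(ok)) { msg <- c(msg, "feature on unknown chromosome"); break }
      lim <- object@seqlens[as.character(seqnames(gr))]
      if (any(start(gr) < 1) || any(end(gr) > lim)) {
        msg <- c(msg, sprintf("'%s' ranges exceed chromosome bounds", nm))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "FeatureModel", function(object) {
  cat("FeatureModel:", length(object@genes), "genes on",
      length(object@seqlens), "chromosome(s),",
      object@flank, "bp promoter/downstream flanks\n")
  bp <- featureBasePairFractions(object)
  cat("  bp fractions:",
      paste(sprintf("%s %.3f", names(bp), bp), collapse = ", "), "\n")
})

#' Accessors for FeatureModel
#'
#' @param x a [FeatureModel-class].
#' @param category one of `"promoter"`, `"five_prime_UTR"`, `"exon"`,
#'   `"intron"`, `"three_prime_UTR"`, `"downstream"`.
#' @return `geneRanges`: gene spans; `featureRanges`: ranges of one category;
#'   `geneBodies`: strand-aware promoter-through-downstream spans (the
#'   "gene body" used for gene-level aggregation); `chromLengths`: the named
#'   length vector.
#' @export
geneRanges <- function(x) { stopifnot(is(x, "FeatureModel")); x@genes }

#' @rdname geneRanges
#' @export
featureRanges <- function(x, category) {
  stopifnot(is(x, "FeatureModel"))
  category <- match.arg(category, setdiff(.FEATURE_CATEGORIES, "intergenic"))
  x@features[[category]]
}

#' @rdname geneRanges
#' @export
chromLengths <- function(x) { stopifnot(is(x, "FeatureModel")); x@seqlens }

#' @rdname geneRanges
#' @export
geneBodies <- function(x) {
  stopifnot(is(x, "FeatureModel"))
  g <- x@genes
  if (!length(g)) return(g)
  lim <- x@seqlens[as.character(seqnames(g))]
  bodies <- GRanges(seqnames(g),
                    IRanges(pmax(1, start(g) - x@flank),
                            pmin(lim, end(g) + x@flank)),
                    strand = strand(g))
  mcols(bodies)$gene_id <- mcols(g)$gene_id
  bodies
}

## ---------------------------------------------------------------------------
## GenotypeMatrix: diploid dosages with a population map
## ---------------------------------------------------------------------------

#' Diploid genotype matrix
#'
#' Alternate-allele dosages in \{0, 1, 2\} (NA = missing) for biallelic SNPs
#' (rows) by individuals (columns), together with locus coordinates, the
#' RAD-locus grouping of SNPs, and the population map.
#'
#' @slot calls integer matrix of dosages, loci x individuals.
#' @slot loci data.frame with columns `locus_id`, `chrom`, `pos` (1-based),
#'   `radlocus`.
#' @slot popmap data.frame with columns `individual`, `site`,
#'   `meta_population`; rows align with the columns of `calls`.
#' @export
setClass("GenotypeMatrix",
  slots = c(calls = "matrix", loci = "data.frame", popmap = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (nrow(object@calls) != nrow(object@loci))
    msg <- c(msg, "rows of 'calls' must match 'loci'")
  if (ncol(object@calls) != nrow(object@popmap))
    msg <- c(msg, "columns of 'calls' must match 'popmap' rows")
  if (!all(c("locus_id", "chrom", "pos", "radlocus") %in% colnames(object@loci)))
    msg <- c(msg, "'loci' needs columns locus_id, chrom, pos, radlocus")
  if (!all(c("individual", "site", "meta_population") %in% colnames(object@popmap)))
    msg <- c(msg, "'popmap' needs columns individual, site, meta_population")
  v <- object@calls[!is.na(object@calls)]
  if (length(v) && !all(v %in% 0:2))
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  if (nrow(object@loci) && any(object@loci$pos < 0))
    msg <- c(msg, "positions must be non-negative")
  if (length(unique(object@popmap$site)) < 2L)
    msg <- c(msg, "at least two populations are required")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls integer matrix of dosages (loci x individuals); dimnames are
#'   taken from `loci$locus_id` and `popmap$individual` when absent.
#' @param loci data.frame of locus coordinates (`locus_id`, `chrom`, `pos`,
#'   `radlocus`).
#' @param popmap data.frame population map (`individual`, `site`,
#'   `meta_population`).
#' @return A [GenotypeMatrix-class].
#' @export
GenotypeMatrix <- function(calls, loci, popmap) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls))) rownames(calls) <- loci$locus_id
  if (is.null(colnames(calls))) colnames(calls) <- popmap$individual
  if (!"meta_population" %in% colnames(popmap))
    popmap$meta_population <- popmap$site
  new("GenotypeMatrix", calls = calls,
      loci = as.data.frame(loci), popmap = as.data.frame(popmap))
}

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@calls), "loci x",
      ncol(object@calls), "individuals in",
      length(unique(object@popmap$site)), "populations\n")
  miss <- mean(is.na(object@calls))
  cat("  missing calls:", sprintf("%.1f%%", 100 * miss), "\n")
})

#' Accessors for GenotypeMatrix
#'
#' @param x a [GenotypeMatrix-class].
#' @return `genotypeCalls`: the dosage matrix; `lociInfo`: the locus table;
#'   `popMap`: the population map.
#' @export
genotypeCalls <- function(x) { stopifnot(is(x, "GenotypeMatrix")); x@calls }

#' @rdname genotypeCalls
#' @export
lociInfo <- function(x) { stopifnot(is(x, "GenotypeMatrix")); x@loci }

#' @rdname genotypeCalls
#' @export
popMap <- function(x) { stopifnot(is(x, "GenotypeMatrix")); x@popmap }
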