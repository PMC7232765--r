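## Weir & Cockerham (1984) theta from diploid genotypes, with the RAD-style
## locus filters applied upstream of estimation, and gene-level reduction.

#' Apply RAD-style locus filters
#'
#' Keeps loci that are (a) genotyped in at least `min_presence` of the
#' individuals in at least `min_pops_passing` populations, (b) have overall
#' minor-allele frequency >= `min_maf` across all called alleles, and
#' (c) when `one_snp_per_radlocus`, are the first SNP (by position) of their
#' RAD locus among those passing (a) and (b). The operation is idempotent and
#' never grows the matrix; it may return an empty matrix.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param min_presence fraction of a population's individuals that must be
#'   genotyped (default 0.65).
#' @param min_pops_passing number of populations that must meet
#'   `min_presence` (default 2).
#' @param min_maf overall minor-allele frequency threshold (default 0.05).
#' @param one_snp_per_radlocus keep a single SNP per RAD locus (default TRUE).
#' @return The filtered [GenotypeMatrix-class].
#' @export
filterLoci <- function(gm, min_presence = 0.65, min_pops_passing = 2L,
                       min_maf = 0.05, one_snp_per_radlocus = TRUE) {
  stopifnot(is(gm, "GenotypeMatrix"))
  calls <- genotypeCalls(gm)
  if (nrow(calls) == 0L) return(gm)
  pops <- factor(popMap(gm)$site)
  called <- !is.na(calls)

  ind <- groupIndicator(pops)                       # individuals x pops
  n_called <- called %*% ind
  n_per_pop <- matrix(rep(colSums(ind), each = nrow(calls)), nrow = nrow(calls))
  pops_passing <- rowSums(n_called / n_per_pop >= min_presence)

  calls0 <- calls; calls0[!called] <- 0L
  alt <- rowSums(calls0)
  tot <- 2 * rowSums(called)
  maf <- pmin(alt / tot, 1 - alt / tot)
  maf[tot == 0] <- 0

  keep <- pops_passing >= min_pops_passing & maf >= min_maf
  loci <- lociInfo(gm)[keep, , drop = FALSE]
  calls <- calls[keep, , drop = FALSE]
  if (one_snp_per_radlocus && nrow(loci) > 0L) {
    ord <- order(loci$radlocus, loci$pos)
    first <- ord[!duplicated(loci$radlocus[ord])]
    first <- sort(first)
    loci <- loci[first, , drop = FALSE]
    calls <- calls[first, , drop = FALSE]
  }
  GenotypeMatrix(calls, loci, popMap(gm))
}

#' Weir--Cockerham variance components for one locus
#'
#' Computes the among-population (`a`), among-individuals-within-population
#' (`b`) and within-individual (`c`) variance components of Weir & Cockerham
#' (1984) from per-population sample sizes, allele frequencies and observed
#' heterozygosities, and theta = a / (a + b + c). Theta is `NA` when the
#' denominator is zero (globally monomorphic locus).
#'
#' @param n per-population diploid sample sizes (length >= 2).
#' @param p per-population alternate-allele frequencies.
#' @param h per-population observed heterozygote proportions.
#' @return A list with `a`, `b`, `c`, `theta`.
#' @examples
#' wcTheta(n = c(10, 10), p = c(1, 0), h = c(0, 0))$theta  # fixed difference: 1
#' @export
wcTheta <- function(n, p, h) {
  if (length(n) < 2L)
    epiStop("epiDiverge_fst_error",
            "theta needs >= 2 populations (got %d)", length(n))
  if (any(p < 0) || any(p > 1))
    epiStop("epiDiverge_fst_error", "allele frequencies must lie in [0, 1]")
  if (any(n < 1))
    epiStop("epiDiverge_fst_error", "population sample sizes must be >= 1")
  comp <- wcComponentsMatrix(matrix(n, 1L), matrix(p, 1L), matrix(h, 1L))
  list(a = comp$a[1L], b = comp$b[1L], c = comp$c[1L], theta = comp$theta[1L])
}

## Vectorized WC84 components over loci (rows). nMat entries of 0 mark a
## population with no calls at that locus; such populations drop out of all
## sums. Loci with fewer than 2 scored populations, or with mean sample size
## <= 1, yield NA components.
wcComponentsMatrix <- function(nMat, pMat, hMat) {
  use <- nMat > 0
  r <- rowSums(use)
  nMat0 <- nMat * use
  sum_n <- rowSums(nMat0)
  nbar <- sum_n / r
  ok <- r >= 2 & nbar > 1
  nc <- (sum_n - rowSums(nMat0^2) / sum_n) / (r - 1)
  pbar <- rowSums(nMat0 * pMat, na.rm = TRUE) / sum_n
  s2 <- rowSums(nMat0 * (pMat - pbar)^2, na.rm = TRUE) / ((r - 1) * nbar)
  hbar <- rowSums(nMat0 * hMat, na.rm = TRUE) / sum_n

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; cc[!ok] <- NA_real_
  denom <- a + b + cc
  theta <- ifelse(!is.na(denom) & denom != 0, a / denom, NA_real_)
  list(a = a, b = b, c = cc, theta = theta, r = r, nbar = nbar)
}

#' Per-locus Weir--Cockerham theta for a genotype matrix
#'
#' Summarizes each locus per population (sample size among called
#' individuals, allele frequency, observed heterozygosity) and computes the
#' WC84 components and theta. Missing genotypes reduce the per-population
#' sample size; populations with no calls at a locus drop out of that locus's
#' sums.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param grouping population-map column to group by (`"site"` or
#'   `"meta_population"`).
#' @return data.frame with columns `locus_id`, `chrom`, `pos`, `radlocus`,
#'   `n_pops`, `a`, `b`, `c`, `theta`.
#' @export
perLocusFst <- function(gm, grouping = c("site", "meta_population")) {
  stopifnot(is(gm, "GenotypeMatrix"))
  grouping <- match.arg(grouping)
  pops <- factor(popMap(gm)[[grouping]])
  if (nlevels(pops) < 2L)
    epiStop("epiDiverge_fst_error", "need >= 2 populations in '%s'", grouping)
  calls <- genotypeCalls(gm)
  called <- !is.na(calls)
  ind <- groupIndicator(pops)
  calls0 <- calls; calls0[!called] <- 0L

  nMat <- called %*% ind                                # per-pop called n
  altMat <- calls0 %*% ind
  pMat <- altMat / (2 * nMat)
  pMat[nMat == 0] <- 0
  hetMat <- (calls0 == 1L & called) %*% ind
  hMat <- hetMat / nMat
  hMat[nMat == 0] <- 0

  comp <- wcComponentsMatrix(nMat, pMat, hMat)
  cbind(lociInfo(gm)[, c("locus_id", "chrom", "pos", "radlocus")],
        data.frame(n_pops = comp$r, a = comp$a, b = comp$b, c = comp$c,
                   theta = comp$theta))
}

#' Summarize theta across loci
#'
#' "Mean F_ST" is ambiguous between the arithmetic mean of per-locus theta
#' values and the ratio of summed components; both are returned. The
#' arithmetic mean over defined loci is the headline statistic.
#'
#' @param fst a per-locus data.frame from [perLocusFst()] (needs columns `a`,
#'   `b`, `c`, `theta`).
#' @return list with `mean_of_thetas`, `ratio_of_sums`, `n_defined`.
#' @export
meanFst <- function(fst) {
  def <- !is.na(fst$theta)
  if (!any(def))
    epiStop("epiDiverge_fst_error", "no locus has a defined theta")
  list(mean_of_thetas = mean(fst$theta[def]),
       ratio_of_sums = sum(fst$a[def]) / sum(fst$a[def] + fst$b[def] + fst$c[def]),
       n_defined = sum(def))
}

#' Gene-level weighted F_ST
#'
#' For each gene body (promoter through 2-kb downstream), combines the loci
#' falling inside it as `sum(a) / sum(a + b + c)` — i.e. weighting each locus
#' by its total variance denominator. Genes containing no loci are absent
#' from the output.
#'
#' @param fst per-locus data.frame from [perLocusFst()].
#' @param model a [FeatureModel-class].
#' @return data.frame with `gene_id`, `n_loci`, `fst`.
#' @export
geneFst <- function(fst, model) {
  stopifnot(is(model, "FeatureModel"))
  bodies <- geneBodies(model)
  if (!length(bodies) || !nrow(fst))
    return(data.frame(gene_id = character(), n_loci = integer(),
                      fst = numeric()))
  def <- !is.na(fst$theta)
  fst <- fst[def, , drop = FALSE]
  gr <- GRanges(fst$chrom, IRanges(fst$pos, width = 1L))
  hit <- findOverlaps(gr, bodies, ignore.strand = TRUE)
  if (!length(hit))
    return(data.frame(gene_id = character(), n_loci = integer(),
                      fst = numeric()))
  gid <- mcols(bodies)$gene_id[S4Vectors::subjectHits(hit)]
  li <- S4Vectors::queryHits(hit)
  agg <- function(v) tapply(v, gid, sum)
  a <- agg(fst$a[li])
  denom <- agg(fst$a[li] + fst$b[li] + fst$c[li])
  data.frame(gene_id = names(a),
             n_loci = as.integer(tapply(li, gid, length)),
             fst = as.numeric(a / denom),
             row.names = NULL, stringsAsFactors = FALSE)
}
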