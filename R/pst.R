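## P_ST: the methylation analogue of F_ST. For a region with per-individual
## methylation fractions grouped by population,
##   P_ST = (Var_Total - Var_Sub) / Var_Total
## where Var_Total is the sample variance (n-1 denominator) across all
## individuals pooled and Var_Sub is the unweighted mean of the
## per-population sample variances. Negative values (sampling noise making
## Var_Sub exceed Var_Total) are retained so means stay unbiased; P_ST is
## undefined (NA) when Var_Total is zero.

#' P_ST for one region
#'
#' @param fractions numeric vector of per-individual methylation fractions
#'   (`NA` = individual not covered in the region).
#' @param populations factor/character of population labels aligned with
#'   `fractions`.
#' @return list with `pst`, `var_total`, `var_sub`, `per_population`
#'   (named vector of per-population sample variances) and `n_used`.
#' @examples
#' pstRegion(c(0.2, 0.4, 0.6, 0.8), c("A", "A", "B", "B"))$pst  # 0.7
#' @export
pstRegion <- function(fractions, populations) {
  populations <- factor(as.character(populations))
  if (length(fractions) != length(populations))
    epiStop("epiDiverge_pst_error", "fractions and labels differ in length")
  res <- pstMatrix(matrix(fractions, nrow = 1L), populations)
  list(pst = res$pst[1L], var_total = res$var_total[1L],
       var_sub = res$var_sub[1L],
       per_population = res$per_population[1L, ],
       n_used = res$n_used[1L])
}

## Vectorized P_ST over regions (rows of `m`); NA entries are uncovered
## individuals. A region needs >= 2 populations with >= 2 defined fractions
## each; otherwise all its outputs are NA.
pstMatrix <- function(m, populations) {
  populations <- factor(as.character(populations))
  if (ncol(m) != length(populations))
    epiStop("epiDiverge_pst_error", "columns of m must match population labels")
  ind <- groupIndicator(populations)
  vg <- rowVarByGroup(m, ind)                       # regions x pops
  n_pop_ok <- rowSums(!is.na(vg))
  all_ind <- matrix(1, ncol(m), 1L)
  vt <- rowVarByGroup(m, all_ind)[, 1L]
  n_used <- rowSums(!is.na(m))
  ok <- n_pop_ok >= 2L & !is.na(vt)
  vs <- rowMeans(vg, na.rm = TRUE)
  vs[!ok] <- NA_real_
  vt[!ok] <- NA_real_
  pst <- (vt - vs) / vt
  pst[!is.na(vt) & vt == 0] <- NA_real_             # undefined, counted upstream
  list(pst = pst, var_total = vt, var_sub = vs, per_population = vg,
       n_used = n_used)
}

#' P_ST for every tile of a tile set
#'
#' Computes per-individual pooled tile fractions (after the coverage and
#' occupancy filters embodied in `tiles`) and the per-tile P_ST across the
#' populations of `grouping`.
#'
#' @param tiles a [MethylTileSet-class].
#' @param grouping colData column or factor (default `"population"`).
#' @return data.frame with `tile`, `chrom`, `start` (0-based), `end`,
#'   `var_total`, `var_sub`, `pst`, `n_used`, and one `var.<pop>` column per
#'   population.
#' @export
pstTiles <- function(tiles, grouping = "population") {
  stopifnot(is(tiles, "MethylTileSet"))
  groups <- resolveGrouping(tiles, grouping)
  res <- pstMatrix(methFraction(tiles), groups)
  rr <- rowRanges(tiles)
  pv <- as.data.frame(res$per_population)
  colnames(pv) <- paste0("var.", colnames(pv))
  data.frame(tile = names(rr) %||% paste0(seqnames(rr), ":", start(rr) - 1L),
             chrom = as.character(seqnames(rr)),
             start = start(rr) - 1L, end = end(rr),
             var_total = res$var_total, var_sub = res$var_sub,
             pst = res$pst, n_used = res$n_used, pv,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate tiles and F_ST to gene level
#'
#' Joins tile-level methylation with gene-level F_ST over gene bodies
#' (promoter through 2-kb downstream). Per gene: the mean of pooled tile
#' percentages (gene-body methylation), the mean of defined tile P_ST
#' values, the weighted gene F_ST, and a DMR flag (any overlapping tile
#' called hyper/hypo). Genes lacking either methylation tiles or SNP loci
#' are excluded from the joint table but listed separately.
#'
#' @param tiles a [MethylTileSet-class].
#' @param pst tile-level data.frame from [pstTiles()].
#' @param model a [FeatureModel-class].
#' @param gene_fst data.frame from [geneFst()].
#' @param dmrs optional data.frame from [dmrTest()] used to flag genes.
#' @return list with `joint` (genes with both data types), `meth_only`,
#'   `fst_only` (character vectors of gene ids).
#' @export
aggregateByGene <- function(tiles, pst, model, gene_fst, dmrs = NULL) {
  stopifnot(is(tiles, "MethylTileSet"), is(model, "FeatureModel"))
  rr <- rowRanges(tiles)
  bodies <- geneBodies(model)
  hit <- findOverlaps(rr, bodies, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hit)
  gid <- mcols(bodies)$gene_id[S4Vectors::subjectHits(hit)]

  pooled <- rowMeans(pooledPercent(tiles), na.rm = TRUE)  # mean over pops
  mean_meth <- tapply(pooled[qh], gid, mean)
  mean_pst <- tapply(pst$pst[qh], gid, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  })
  n_tiles <- tapply(qh, gid, length)

  dmr_genes <- character(0)
  if (!is.null(dmrs) && nrow(dmrs)) {
    sig <- dmrs[dmrs$call != "ns", , drop = FALSE]
    if (nrow(sig)) {
      sgr <- GRanges(sig$chrom, IRanges(sig$start + 1L, sig$end))
      shit <- findOverlaps(sgr, bodies, ignore.strand = TRUE)
      dmr_genes <- unique(mcols(bodies)$gene_id[S4Vectors::subjectHits(shit)])
    }
  }
  meth_tab <- data.frame(gene_id = names(mean_meth),
                         n_tiles = as.integer(n_tiles),
                         mean_meth_pct = as.numeric(mean_meth),
                         mean_pst = as.numeric(mean_pst),
                         stringsAsFactors = FALSE)
  joint <- merge(meth_tab, gene_fst, by = "gene_id")
  joint$dmr <- joint$gene_id %in% dmr_genes
  list(joint = joint[order(joint$gene_id), , drop = FALSE],
       meth_only = setdiff(meth_tab$gene_id, gene_fst$gene_id),
       fst_only = setdiff(gene_fst$gene_id, meth_tab$gene_id))
}

#' Joint divergence summary
#'
#' Summarizes the P_ST--F_ST comparison: the two means, their ratio, Pearson
#' and Spearman correlations between per-gene P_ST and F_ST (NA and flagged
#' when either column is constant), and a two-sample KS test comparing the
#' gene-level F_ST of DMR-flagged genes against all genes (skipped with a
#' note when no gene is DMR-flagged).
#'
#' @param joint the `joint` table from [aggregateByGene()] (needs columns
#'   `mean_pst`, `fst`, `dmr`).
#' @param tile_pst optional tile-level P_ST table ([pstTiles()]); when given,
#'   `mean_pst_tiles` over defined tiles is reported as the headline mean.
#' @return list of summary statistics.
#' @export
divergenceSummary <- function(joint, tile_pst = NULL) {
  if (nrow(joint) < 2L)
    epiStop("epiDiverge_summary_error", "need >= 2 joint rows")
  mp <- mean(joint$mean_pst, na.rm = TRUE)
  mf <- mean(joint$fst, na.rm = TRUE)
  out <- list(mean_pst_genes = mp, mean_fst_genes = mf)
  if (!is.null(tile_pst)) {
    out$mean_pst_tiles <- mean(tile_pst$pst, na.rm = TRUE)
    out$n_tiles_defined <- sum(!is.na(tile_pst$pst))
    out$n_tiles_undefined <- sum(is.na(tile_pst$pst))
  }
  headline_pst <- out$mean_pst_tiles %||% mp
  out$pst_fst_ratio <- headline_pst / mf
  ok <- complete.cases(joint$mean_pst, joint$fst)
  if (sum(ok) >= 3L && stats::sd(joint$mean_pst[ok]) > 0 &&
      stats::sd(joint$fst[ok]) > 0) {
    out$pearson <- cor(joint$mean_pst[ok], joint$fst[ok], method = "pearson")
    out$spearman <- cor(joint$mean_pst[ok], joint$fst[ok], method = "spearman")
    out$correlation_note <- NA_character_
  } else {
    out$pearson <- NA_real_
    out$spearman <- NA_real_
    out$correlation_note <- "correlation undefined (constant column or < 3 rows)"
  }
  dmr_fst <- joint$fst[joint$dmr %in% TRUE]
  if (length(dmr_fst)) {
    ks <- suppressWarnings(ks.test(dmr_fst, joint$fst))
    out$ks_dmr_vs_all_D <- unname(ks$statistic)
    out$ks_dmr_vs_all_p <- ks$p.value
    out$ks_note <- NA_character_
  } else {
    out$ks_dmr_vs_all_D <- NA_real_
    out$ks_dmr_vs_all_p <- NA_real_
    out$ks_note <- "no DMR-flagged genes; KS comparison skipped"
  }
  out
}
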