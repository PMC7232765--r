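## Tile-level differential-methylation testing between two groups.
##
## Test statistic: likelihood-ratio test of the group term in a binomial
## logistic model on per-individual (methylated, total) counts. With a single
## factor covariate the MLE fitted proportion of each group is its pooled
## count fraction, so the LRT has a closed form, computed here directly (it
## equals the glm(cbind(meth, unmeth) ~ group, binomial) deviance test).
## Groups reduced to one covered sample fall back to an exact 2x2 test on
## pooled counts.

## x*log(p) with the 0*log(0) := 0 convention
.xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))

.binomLL <- function(m, tot, p) .xlogy(m, p) + .xlogy(tot - m, 1 - p)

#' Call differentially methylated regions between two groups
#'
#' For each tile, tests the group effect on per-individual methylation counts
#' with a binomial-logistic likelihood-ratio test (1 df); p-values are
#' Benjamini--Hochberg adjusted across all tested tiles of the comparison.
#' The methylation difference is the difference of coverage-pooled group
#' percentages, oriented `group1 - group2`. A tile is called `hyper`
#' (or `hypo`) only when both `|meth_diff| >= diff_threshold` and
#' `q <= q_threshold`; otherwise `ns`.
#'
#' @param tiles a [MethylTileSet-class].
#' @param group1,group2 levels of `grouping` to compare; `group1` is the
#'   focal group whose excess methylation is "hyper".
#' @param grouping colData column name or factor (default `"population"`).
#' @param diff_threshold minimum absolute difference in percentage points
#'   (default 15).
#' @param q_threshold maximum BH-adjusted p-value (default 0.05).
#' @param min_individuals_per_group occupancy rule re-applied to the pair
#'   (default 8; use 0 if `tiles` is already restricted).
#' @return data.frame with columns `tile`, `chrom`, `start` (0-based), `end`,
#'   `mean1`, `mean2` (pooled percents), `meth_diff`, `pvalue`, `qvalue`,
#'   `call`.
#' @export
dmrTest <- function(tiles, group1, group2, grouping = "population",
                    diff_threshold = 15, q_threshold = 0.05,
                    min_individuals_per_group = 8L) {
  stopifnot(is(tiles, "MethylTileSet"))
  groups <- resolveGrouping(tiles, grouping)
  for (g in c(group1, group2))
    if (!g %in% levels(groups))
      epiStop("epiDiverge_dmr_error", "unknown group '%s'", g)
  sel <- groups %in% c(group1, group2)
  tiles <- tiles[, sel]
  groups <- droplevels(groups[sel])
  if (min_individuals_per_group > 0L)
    tiles <- occupancyFilter(tiles, groups, NULL, min_individuals_per_group)
  if (!nrow(tiles))
    return(data.frame(tile = character(), chrom = character(),
                      start = integer(), end = integer(),
                      mean1 = numeric(), mean2 = numeric(),
                      meth_diff = numeric(), pvalue = numeric(),
                      qvalue = numeric(), call = character()))
  m <- assay(tiles, "meth"); tt <- assay(tiles, "total")
  g1 <- which(as.character(groups) == group1)
  g2 <- which(as.character(groups) == group2)

  sum1m <- rowSums(m[, g1, drop = FALSE]); sum1t <- rowSums(tt[, g1, drop = FALSE])
  sum2m <- rowSums(m[, g2, drop = FALSE]); sum2t <- rowSums(tt[, g2, drop = FALSE])
  zero_grp <- sum1t == 0 | sum2t == 0
  if (any(zero_grp)) {
    warning(sum(zero_grp), " tile(s) with zero total reads in a group excluded")
    keep <- !zero_grp
    tiles <- tiles[keep, ]
    m <- m[keep, , drop = FALSE]; tt <- tt[keep, , drop = FALSE]
    sum1m <- sum1m[keep]; sum1t <- sum1t[keep]
    sum2m <- sum2m[keep]; sum2t <- sum2t[keep]
  }
  n_cov1 <- rowSums(tt[, g1, drop = FALSE] > 0)
  n_cov2 <- rowSums(tt[, g2, drop = FALSE] > 0)

  p1 <- sum1m / sum1t; p2 <- sum2m / sum2t
  p0 <- (sum1m + sum2m) / (sum1t + sum2t)
  ## closed-form LRT on the pooled sufficient statistics
  ll_alt <- .binomLL(sum1m, sum1t, p1) + .binomLL(sum2m, sum2t, p2)
  ll_null <- .binomLL(sum1m + sum2m, sum1t + sum2t, p0)
  lrt <- pmax(0, 2 * (ll_alt - ll_null))
  pval <- pchisq(lrt, df = 1L, lower.tail = FALSE)

  exact <- which(n_cov1 < 2L | n_cov2 < 2L)
  for (i in exact) {
    tab <- matrix(c(sum1m[i], sum1t[i] - sum1m[i],
                    sum2m[i], sum2t[i] - sum2m[i]), 2L, byrow = TRUE)
    pval[i] <- fisher.test(tab)$p.value
  }
  qval <- p.adjust(pval, method = "BH")
  meth_diff <- 100 * (p1 - p2)
  call <- rep("ns", length(pval))
  sig <- qval <= q_threshold & abs(meth_diff) >= diff_threshold
  call[sig & meth_diff > 0] <- "hyper"
  call[sig & meth_diff < 0] <- "hypo"
  rr <- rowRanges(tiles)
  data.frame(tile = names(rr) %||% paste0(seqnames(rr), ":", start(rr) - 1L),
             chrom = as.character(seqnames(rr)),
             start = start(rr) - 1L, end = end(rr),
             mean1 = 100 * p1, mean2 = 100 * p2,
             meth_diff = meth_diff, pvalue = pval, qvalue = qval,
             call = call, row.names = NULL, stringsAsFactors = FALSE)
}

#' Hierarchical clustering and principal components of sample methylomes
#'
#' Restricts to tiles covered in every sample ("shared" tiles), computes
#' per-sample methylation-fraction vectors, clusters samples with Ward's
#' method on 1 - Pearson correlation distances, and returns principal
#' components of the centered fraction matrix.
#'
#' @param tiles a [MethylTileSet-class] with >= 3 samples.
#' @return list with `dendrogram` (an `hclust`), `scores` (samples x PCs),
#'   `sdev`, `n_shared_tiles`, and `distance` (the `dist` used).
#' @export
clusterAndProject <- function(tiles) {
  stopifnot(is(tiles, "MethylTileSet"))
  if (ncol(tiles) < 3L)
    epiStop("epiDiverge_cluster_error", "need >= 3 samples (got %d)", ncol(tiles))
  tt <- assay(tiles, "total")
  shared <- rowSums(tt == 0) == 0L
  if (sum(shared) < 2L)
    epiStop("epiDiverge_cluster_error",
            "need >= 2 tiles shared by all samples (got %d)", sum(shared))
  f <- methFraction(tiles)[shared, , drop = FALSE]
  sds <- apply(f, 2L, stats::sd)
  if (any(sds == 0))
    epiStop("epiDiverge_cluster_error",
            "constant methylation vector (correlation undefined) for sample(s): %s",
            paste(colnames(f)[sds == 0], collapse = ", "))
  d <- as.dist(1 - cor(f))
  hc <- hclust(d, method = "ward.D")
  pc <- prcomp(t(f), center = TRUE, scale. = FALSE)
  list(dendrogram = hc, scores = pc$x, sdev = pc$sdev,
       n_shared_tiles = sum(shared), distance = d)
}
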