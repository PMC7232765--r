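test_that("P_ST worked examples evaluate exactly", {
  res <- pstRegion(c(0.2, 0.4, 0.6, 0.8), c("A", "A", "B", "B"))
  expect_equal(res$var_sub, 0.02, tolerance = 1e-12)
  expect_equal(res$var_total, 0.2 / 3, tolerance = 1e-12)
  expect_equal(res$pst, 0.7, tolerance = 1e-12)
  expect_equal(unname(res$per_population), c(0.02, 0.02), tolerance = 1e-12)
  ## all individuals identical: undefined
  expect_true(is.na(pstRegion(rep(0.5, 6), rep(c("A", "B"), 3))$pst))
  ## zero within-population variance: P_ST = 1
  expect_equal(pstRegion(c(0.3, 0.3, 0.7, 0.7), c("A", "A", "B", "B"))$pst, 1)
})

test_that("P_ST matches a direct-summation variance oracle on random cases", {
  set.seed(515)
  for (i in 1:1000) {
    k <- sample(2:4, 1)
    n <- sample(2:8, k, replace = TRUE)
    pops <- rep(sprintf("P%d", seq_len(k)), n)
    f <- runif(sum(n))
    f[sample(length(f), rbinom(1, 2, 0.3))] <- NA  # some uncovered
    got <- pstRegion(f, pops)$pst
    want <- pst_oracle(f, pops)
    ## the oracle goes undefined when missingness leaves < 2 pops with >= 2
    if (is.na(want)) expect_true(is.na(got)) else
      expect_lt(abs(got - want), 1e-12)
  }
})

test_that("P_ST is invariant to common affine rescaling of the fractions", {
  set.seed(616)
  for (i in 1:50) {
    f <- runif(12)
    pops <- rep(c("A", "B", "C"), each = 4)
    a <- runif(1, 0.2, 3); b <- runif(1, -1, 1)
    expect_equal(pstRegion(a * f + b, pops)$pst, pstRegion(f, pops)$pst,
                 tolerance = 1e-9)
  }
})

test_that("tile-level P_ST flows through tile sets with uncovered cells", {
  pop <- c("A", "A", "A", "B", "B", "B")
  tt <- matrix(10L, 2L, 6L)
  tt[2L, 1L] <- 0L                               # uncovered individual
  m <- matrix(as.integer(round(10 * c(
    0.2, 0.4, 0.3, 0.6, 0.8, 0.7,
    0.5, 0.5, 0.5, 0.5, 0.5, 0.5))), 2L, byrow = TRUE)
  m[2L, 1L] <- 0L
  ts <- make_tileset(m, tt, population = pop)
  out <- pstTiles(ts)
  f1 <- m[1, ] / 10
  expect_equal(out$pst[1], pst_oracle(f1, pop), tolerance = 1e-12)
  expect_true(is.na(out$pst[2]))                 # constant -> undefined
  expect_equal(out$n_used, c(6L, 5L))
  expect_true(all(c("var.A", "var.B") %in% colnames(out)))
})

test_that("gene aggregation joins methylation and F_ST and flags DMR genes", {
  gff <- write_gff(list(
    list(id = "g1", strand = "+", start = 2001L, end = 2500L),
    list(id = "g2", strand = "+", start = 9001L, end = 9500L)),
    chrom_len = 2e4)
  model <- buildFeatureModel(gff)
  ## tiles 1-2 in g1's body, tile 3 in g2's body
  pop <- c("A", "A", "B", "B")
  tt <- matrix(20L, 3L, 4L)
  m <- matrix(as.integer(round(20 * c(
    0.2, 0.3, 0.6, 0.7,
    0.3, 0.4, 0.8, 0.9,
    0.5, 0.6, 0.5, 0.4))), 3L, byrow = TRUE)
  ts0 <- make_tileset(m, tt, population = pop)
  ## place tiles at [2000,2100), [2100,2200), [9000,9100) (0-based)
  rr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(2001L, 2101L, 9001L), width = 100L))
  names(rr) <- sprintf("chr1:%d", GenomicRanges::start(rr) - 1L)
  SummarizedExperiment::rowRanges(ts0) <- rr
  ts <- ts0
  pst <- pstTiles(ts)
  gene_fst <- data.frame(gene_id = c("g1", "g3"), n_loci = c(2L, 1L),
                         fst = c(0.3, 0.1))
  dmrs <- data.frame(chrom = "chr1", start = 2100L, end = 2200L,
                     call = "hyper")
  agg <- aggregateByGene(ts, pst, model, gene_fst, dmrs = dmrs)
  expect_identical(agg$joint$gene_id, "g1")      # only g1 has both data types
  expect_equal(agg$joint$mean_pst, mean(pst$pst[1:2]), tolerance = 1e-12)
  pooled <- rowMeans(pooledPercent(ts))
  expect_equal(agg$joint$mean_meth_pct, mean(pooled[1:2]), tolerance = 1e-12)
  expect_true(agg$joint$dmr)
  expect_identical(agg$meth_only, "g2")
  expect_identical(agg$fst_only, "g3")
  ## a gene with a single tile reports that tile's values
  agg1 <- aggregateByGene(ts[3, ], pst[3, ], model,
                          data.frame(gene_id = "g2", n_loci = 1L, fst = 0.2))
  expect_equal(agg1$joint$mean_pst, pst$pst[3], tolerance = 1e-12)
  ## mean over defined tile P_ST values: direct arithmetic
  expect_equal(mean(c(0.2, 0.4)), 0.3)
})

test_that("the divergence summary reports means, ratio, correlations and KS", {
  joint <- data.frame(gene_id = sprintf("g%d", 1:6),
                      mean_pst = c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1),
                      fst = rep(0.02, 6), dmr = FALSE)
  s <- divergenceSummary(joint)
  expect_equal(s$mean_pst_genes, 0.1)
  expect_equal(s$mean_fst_genes, 0.02)
  expect_equal(s$pst_fst_ratio, 5)
  expect_true(is.na(s$pearson))                 # constant columns flagged
  expect_match(s$correlation_note, "undefined")
  expect_match(s$ks_note, "skipped")

  set.seed(71)
  joint2 <- data.frame(gene_id = sprintf("g%d", 1:40),
                       mean_pst = runif(40), fst = runif(40, 0, 0.1),
                       dmr = rep(c(TRUE, FALSE), 20))
  s2 <- divergenceSummary(joint2)
  expect_false(is.na(s2$pearson))
  ## DMR F_ST drawn from the same distribution: D stays small
  expect_lt(s2$ks_dmr_vs_all_D, 0.5)
  expect_gt(s2$ks_dmr_vs_all_p, 0.01)
  expect_error(divergenceSummary(joint2[1, ]), ">= 2")
})
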