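test_that("promoters and downstream flanks are strand-aware and clipped", {
  ## minus-strand gene occupying 0-based [5000, 8000): 1-based 5001..8000;
  ## its promoter is the 2 kb after the gene end, 0-based [8000, 10000)
  gff <- write_gff(list(
    list(id = "gMinus", strand = "-", start = 5001L, end = 8000L),
    list(id = "gEdge", strand = "+", start = 1L, end = 900L),
    list(id = "gNear", strand = "+", start = 12001L, end = 13000L)),
    chrom_len = 2e4)
  model <- buildFeatureModel(gff)
  prom <- featureRanges(model, "promoter")
  pm <- prom[S4Vectors::mcols(prom)$gene_id == "gMinus"]
  expect_equal(GenomicRanges::start(pm), 8001L)
  expect_equal(GenomicRanges::end(pm), 10000L)
  ## a gene at the chromosome start has no room for a promoter
  expect_false("gEdge" %in%
    S4Vectors::mcols(prom)$gene_id[GenomicRanges::width(prom) > 0])
  ## gNear promoter is clipped against nothing: full 2 kb
  pn <- prom[S4Vectors::mcols(prom)$gene_id == "gNear"]
  expect_equal(GenomicRanges::start(pn), 10001L)
  expect_equal(GenomicRanges::end(pn), 12000L)
  ## downstream of gEdge (plus strand) begins right after its end
  dn <- featureRanges(model, "downstream")
  de <- dn[S4Vectors::mcols(dn)$gene_id == "gEdge"]
  expect_equal(GenomicRanges::start(de), 901L)
})

test_that("single-exon genes have no introns; multi-exon genes do", {
  gff <- write_gff(list(
    list(id = "gOne", strand = "+", start = 1001L, end = 2000L),
    list(id = "gTwo", strand = "+", start = 5001L, end = 7000L,
         exons = list(c(5001L, 5400L), c(6601L, 7000L)))),
    chrom_len = 1e4)
  model <- buildFeatureModel(gff)
  introns <- featureRanges(model, "intron")
  expect_false("gOne" %in% S4Vectors::mcols(introns)$gene_id)
  it <- introns[S4Vectors::mcols(introns)$gene_id == "gTwo"]
  expect_equal(GenomicRanges::start(it), 5401L)
  expect_equal(GenomicRanges::end(it), 6600L)
  ## an exon escaping its gene span is rejected
  bad <- write_gff(list(list(id = "gBad", strand = "+", start = 100L,
                             end = 200L, exons = list(c(100L, 300L)))),
                   chrom_len = 1e3)
  expect_error(buildFeatureModel(bad), "exon outside")
})

test_that("tiles classify by maximal overlap with precedence and nearest gene", {
  gff <- write_gff(list(
    list(id = "gA", strand = "+", start = 5001L, end = 8000L,
         exons = list(c(5001L, 5500L), c(7501L, 8000L)),
         utr5 = list(c(5001L, 5200L)))),
    chrom_len = 2e4)
  model <- buildFeatureModel(gff)
  tiles <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(6001L, 4501L, 15001L, 5101L),
    width = c(100L, 100L, 100L, 40L)))
  cls <- classifyRegions(tiles, model)
  expect_equal(as.character(cls$category),
               c("intron",      # wholly inside the intron
                 "promoter",    # 500 bp upstream of the gene start
                 "intergenic",  # > 2 kb from every gene
                 "five_prime_UTR"))  # UTR ties its enclosing exon: precedence
  expect_equal(cls$gene_id, c("gA", "gA", "gA", "gA"))
  err <- tryCatch(classifyRegions(
    GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 100)), model),
    error = identity)
  expect_match(conditionMessage(err), "unknown chromosome")
})

test_that("feature distributions are proper and KS follows the category CDFs", {
  d <- featureDistribution(c("exon", "exon", "intron", "intergenic"))
  expect_equal(sum(d), 1, tolerance = 1e-12)
  expect_equal(unname(d["exon"]), 0.5)
  expect_equal(attr(d, "n_tiles"), 4L)

  same <- compareFeatureDistributions(d, d)
  expect_equal(same$D, 0)
  expect_equal(same$p_value, 1)

  a <- c(1, 0, 0, 0, 0, 0, 0); b <- c(0, 0, 0, 0, 0, 0, 1)
  res <- compareFeatureDistributions(a, b, n1 = 100L, n2 = 100L)
  expect_equal(res$D, 1)
  expect_lt(res$p_value, 1e-6)
  expect_error(compareFeatureDistributions(a, b[1:3]), "length")

  set.seed(11)
  for (i in 1:25) {
    p <- runif(7); q <- runif(7)
    got <- compareFeatureDistributions(p, q, n1 = 500L, n2 = 500L)$D
    expect_equal(got, ks_d_categorical_oracle(p, q), tolerance = 1e-12)
  }
  ## the expanded-sample ECDF route agrees too
  p <- c(2, 1, 1, 0, 0, 1, 3); q <- c(1, 1, 1, 1, 1, 1, 2)
  x <- rep(1:7, p * 10); y <- rep(1:7, q * 10)
  expect_equal(compareFeatureDistributions(p, q)$D, ks_d_oracle(x, y),
               tolerance = 1e-12)
})

test_that("random tile sets are reproducible, in bounds, and unbiased", {
  cfg <- simConfig(n_tiles = 100L, seed = 8L)   # default 1 Mb / 100 genes
  gff <- tempfile(fileext = ".gff3")
  simulateGenomeAnnotation(cfg, gff)
  model <- buildFeatureModel(gff)

  s1 <- generateRandomTiles(model, n_per_set = 200L, n_sets = 2L, seed = 4L)
  s2 <- generateRandomTiles(model, n_per_set = 200L, n_sets = 2L, seed = 4L)
  expect_identical(lapply(s1, GenomicRanges::start),
                   lapply(s2, GenomicRanges::start))
  expect_true(all(vapply(s1, function(g)
    all(GenomicRanges::start(g) >= 1 & GenomicRanges::end(g) <= 1e6), TRUE)))
  expect_error(generateRandomTiles(model, n_per_set = 0L), "n_per_set")

  sets <- generateRandomTiles(model, n_per_set = 2000L, n_sets = 6L, seed = 9L)
  fracs <- vapply(sets, function(g)
    featureDistribution(classifyRegions(g, model)$category),
    numeric(7))
  bp <- featureBasePairFractions(model)
  ## mean per-category fraction over the 6 sets tracks the exact bp fraction
  expect_true(all(abs(rowMeans(fracs) - bp) <= 0.02))
})
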