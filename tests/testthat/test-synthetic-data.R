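test_that("generators are byte-identical under a fixed seed", {
  cfg <- simConfig(n_loci = 40L, n_individuals_per_pop = 4L, n_tiles = 12L,
                   n_genes = 5L, genome_length = 5e4, missing_rate = 0.1,
                   seed = 99L)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  simulateGenotypes(cfg, d1); simulateGenotypes(cfg, d2)
  simulateMethylomes(cfg, d1); simulateMethylomes(cfg, d2)
  simulateGenomeAnnotation(cfg, file.path(d1, "ann.gff3"))
  simulateGenomeAnnotation(cfg, file.path(d2, "ann.gff3"))
  simulateSalinitySeries(c(A = 20, B = 5), 2, 30L, seed = 99L,
                         path = file.path(d1, "sal.csv"))
  simulateSalinitySeries(c(A = 20, B = 5), 2, 30L, seed = 99L,
                         path = file.path(d2, "sal.csv"))
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("simulated files round-trip through the pipeline readers", {
  cfg <- simConfig(n_loci = 30L, n_individuals_per_pop = 3L, n_tiles = 10L,
                   missing_rate = 0.2, n_genes = 4L, genome_length = 5e4,
                   seed = 7L)
  dir <- file.path(tempdir(), "sim_rt")
  sim <- simulateGenotypes(cfg, dir)
  simulateMethylomes(cfg, file.path(dir, "cov"))
  simulateGenomeAnnotation(cfg, file.path(dir, "ann.gff3"))

  pm <- readPopMap(file.path(dir, "popmap.tsv"))
  expect_identical(pm, popMap(sim$genotypes))

  tsv <- readGenotypeTsv(file.path(dir, "genotypes.tsv"), pm)
  expect_identical(genotypeCalls(tsv), genotypeCalls(sim$genotypes))
  vcf <- readGenotypesVcf(file.path(dir, "genotypes.vcf"), pm)
  expect_identical(unname(genotypeCalls(vcf)),
                   unname(genotypeCalls(sim$genotypes)))
  expect_identical(lociInfo(vcf)$pos, lociInfo(sim$genotypes)$pos)

  covs <- lapply(list.files(file.path(dir, "cov"), full.names = TRUE),
                 readBismarkCoverage)
  expect_length(covs, nrow(pm))
  ## no records lost: reader totals match the written files line counts
  nlines <- vapply(list.files(file.path(dir, "cov"), full.names = TRUE),
                   function(f) length(readLines(f)), 0L)
  expect_identical(unname(vapply(covs, length, 0L)), unname(nlines))

  model <- buildFeatureModel(file.path(dir, "ann.gff3"))
  expect_s4_class(model, "FeatureModel")
  expect_length(geneRanges(model), cfg@n_genes)
  unlink(dir, recursive = TRUE)
})

test_that("degenerate divergence and empty populations are rejected", {
  expect_error(simConfig(divergence_F = 0), "divergence_F")
  expect_error(simConfig(divergence_F = 1), "divergence_F")
  expect_error(simConfig(n_individuals_per_pop = 0L), "n_individuals_per_pop")
  cfg1 <- simConfig(n_populations = 1L, n_loci = 10L)
  expect_error(simulateGenotypes(cfg1), "at least 2 populations")
})

test_that("near-zero divergence yields near-zero mean theta", {
  cfg <- simConfig(n_loci = 800L, n_individuals_per_pop = 30L,
                   divergence_F = 1e-6, seed = 21L)
  gm <- simulateGenotypes(cfg)$genotypes
  fst <- perLocusFst(gm)
  expect_lt(abs(meanFst(fst)$mean_of_thetas), 0.005)
})

test_that("zero between-population variance yields near-zero mean P_ST", {
  cfg <- simConfig(n_tiles = 2000L, sigma_between = 0, seed = 13L)
  fr <- simulateTileFractions(cfg)
  pops <- rep(c("LC", "LF", "SL", "VB"), each = cfg@n_individuals_per_pop)
  res <- epiDiverge:::pstMatrix(fr, pops)
  expect_lt(abs(mean(res$pst, na.rm = TRUE)), 0.02)
})

test_that("heavy truncation of methylation fractions triggers a warning", {
  cfg <- simConfig(n_tiles = 50L, base_mean_range = c(0.01, 0.05),
                   sigma_within = 0.3, seed = 2L)
  expect_warning(simulateTileFractions(cfg), "truncated")
})

test_that("annotation respects bounds and n_genes = 0 means all intergenic", {
  cfg <- simConfig(n_genes = 8L, genome_length = 1e5, n_tiles = 100L,
                   seed = 17L)
  gff <- tempfile(fileext = ".gff3")
  simulateGenomeAnnotation(cfg, gff)
  model <- buildFeatureModel(gff)
  for (cat_nm in c("promoter", "five_prime_UTR", "exon", "intron",
                   "three_prime_UTR", "downstream")) {
    fr <- featureRanges(model, cat_nm)
    if (length(fr)) {
      expect_true(all(GenomicRanges::start(fr) >= 1))
      expect_true(all(GenomicRanges::end(fr) <= 1e5))
    }
  }
  bp <- featureBasePairFractions(model)
  expect_equal(sum(bp), 1, tolerance = 1e-9)

  cfg0 <- simConfig(n_genes = 0L, genome_length = 1e5, n_tiles = 100L)
  lines <- simulateGenomeAnnotation(cfg0)
  gff0 <- tempfile(fileext = ".gff3"); writeLines(lines, gff0)
  ## no genes: classification of any tile is intergenic; model build rejects
  expect_error(buildFeatureModel(gff0), "no gene features")

  ## packing failure is a named error
  expect_error(
    simulateGenomeAnnotation(simConfig(n_genes = 200L, genome_length = 5e4,
                                       n_tiles = 10L)),
    "cannot pack")
})

test_that("salinity series recover their site means at CLT scale", {
  n_days <- 200L; noise <- 2
  sal <- simulateSalinitySeries(c(X = 15, Y = 8), noise_sd = noise,
                                n_days = n_days, seed = 31L)
  for (s in c("X", "Y")) {
    m <- mean(sal$psu[sal$site == s])
    expect_lt(abs(m - c(X = 15, Y = 8)[[s]]), 3 * noise / sqrt(n_days))
  }
  expect_error(simulateSalinitySeries(c(X = 10), n_days = 5L), "n_days")
  ## zero noise: every day in the matching bin
  sal0 <- simulateSalinitySeries(c(Z = 25), noise_sd = 0, n_days = 20L,
                                 seed = 1L)
  fr <- binSalinityFractions(sal0$psu)$fractions
  expect_equal(unname(fr["psu_gt_20"]), 1)
})
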