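test_that("coverage parsing handles both dialects and rejects bad lines", {
  p <- write_cov(c("chr1\t100\t101\t50.0\t5\t5",
                   "chr1\t180\t181\t20.0\t2\t8"))
  cov <- readBismarkCoverage(p, individual = "a", dialect = "zero_based")
  s <- cpgSites(cov)
  expect_equal(GenomicRanges::start(s), c(101L, 181L))   # internal 1-based
  expect_equal(S4Vectors::mcols(s)$meth, c(5L, 2L))
  ## one_based dialect at printed position 101 lands on the same site
  p2 <- write_cov("chr1\t101\t101\t50.0\t5\t5")
  cov2 <- readBismarkCoverage(p2, individual = "a", dialect = "one_based")
  expect_equal(GenomicRanges::start(cpgSites(cov2)), 101L)

  expect_warning(readBismarkCoverage(write_cov(character(0))), "empty")
  err <- tryCatch(readBismarkCoverage(write_cov("chr1\t1\t2\t50")),
                  error = identity)
  expect_match(conditionMessage(err), "line 1")
  expect_error(readBismarkCoverage(write_cov("chr1\t1\t2\t0\t-3\t2")),
               "negative")
})

test_that("coverage filter keeps the 10-read boundary and 0 is identity", {
  p <- write_cov(c(cov_line("chr1", 100L, 4L, 5L),    # 9 reads
                   cov_line("chr1", 200L, 5L, 5L),    # 10 reads
                   cov_line("chr1", 300L, 20L, 5L)))
  cov <- readBismarkCoverage(p)
  expect_equal(length(filterByCoverage(cov, 10L)), 2L)
  expect_equal(GenomicRanges::start(cpgSites(filterByCoverage(cov, 10L)))[1],
               201L)
  expect_equal(length(filterByCoverage(cov, 0L)), 3L)
})

test_that("tiling pools counts into [start, start+100) windows", {
  p <- write_cov(c(cov_line("chr1", 105L, 5L, 5L),
                   cov_line("chr1", 180L, 2L, 8L)))
  cov <- readBismarkCoverage(p, individual = "P1_01")
  pm <- data.frame(individual = "P1_01", site = "P1",
                   meta_population = "pop1")
  ts <- makeTiles(list(cov), pm, min_individuals_per_group = 1L)
  expect_equal(nrow(ts), 1L)
  rr <- SummarizedExperiment::rowRanges(ts)
  expect_equal(GenomicRanges::start(rr), 101L)  # 0-based tile [100, 200)
  expect_equal(GenomicRanges::end(rr), 200L)
  expect_equal(as.vector(SummarizedExperiment::assay(ts, "meth")), 7L)
  expect_equal(as.vector(SummarizedExperiment::assay(ts, "total")), 20L)
  expect_equal(as.vector(pooledPercent(ts, "population")), 35)
})

test_that("the occupancy rule drops under-covered tiles and small groups error", {
  set.seed(5)
  pm <- make_popmap(k = 2L, n = 10L)
  covs <- lapply(seq_len(20L), function(i) {
    ## tile [0,100): everyone covered; tile [100,200): only 7 of group P1
    starts <- c(10L, if (i <= 7 || i > 10) 110L)
    new("CpGCoverage", individual = pm$individual[i],
        sites = GenomicRanges::GRanges("chr1",
          IRanges::IRanges(starts + 1L, width = 1L),
          meth = rep(3L, length(starts)), unmeth = rep(7L, length(starts))))
  })
  ts <- makeTiles(covs, pm, min_individuals_per_group = 8L)
  expect_equal(nrow(ts), 1L)
  expect_equal(GenomicRanges::start(SummarizedExperiment::rowRanges(ts)), 1L)
  expect_error(makeTiles(covs, pm, min_individuals_per_group = 11L),
               "smaller than the occupancy threshold")
  ## no CpGs at all -> no tiles
  empty <- lapply(pm$individual, function(id)
    new("CpGCoverage", individual = id,
        sites = GenomicRanges::GRanges(meth = integer(0),
                                       unmeth = integer(0))))
  expect_equal(nrow(makeTiles(empty, pm, min_individuals_per_group = 0L)), 0L)
})

test_that("tiling conserves read counts on random fixtures", {
  set.seed(77)
  pm <- make_popmap(k = 2L, n = 3L)
  covs <- lapply(pm$individual, function(id) {
    n <- sample(30:60, 1)
    pos0 <- sort(sample(0:2999, n))
    m <- rpois(n, 4); u <- rpois(n, 6)
    new("CpGCoverage", individual = id,
        sites = GenomicRanges::GRanges("chr1",
          IRanges::IRanges(pos0 + 1L, width = 1L),
          meth = as.integer(m), unmeth = as.integer(u)))
  })
  ts <- makeTiles(covs, pm, min_individuals_per_group = 0L)
  for (i in seq_along(covs)) {
    s <- cpgSites(covs[[i]])
    expect_equal(sum(SummarizedExperiment::assay(ts, "meth")[, i]),
                 sum(S4Vectors::mcols(s)$meth))
    expect_equal(sum(SummarizedExperiment::assay(ts, "total")[, i]),
                 sum(S4Vectors::mcols(s)$meth + S4Vectors::mcols(s)$unmeth))
  }
})

test_that("identical groups give zero difference and ns calls", {
  m <- matrix(rep(c(5L, 3L, 7L), times = 4L), 3L)   # same counts per sample
  tt <- matrix(10L, 3L, 4L)
  ts <- make_tileset(m, tt, population = c("A", "A", "B", "B"))
  dd <- dmrTest(ts, "A", "B", min_individuals_per_group = 2L)
  expect_equal(dd$meth_diff, rep(0, 3))
  expect_true(all(dd$call == "ns"))
})

test_that("a strong two-group shift is called hyper with q below 0.05", {
  m <- matrix(c(9L, 9L, 1L, 1L), 1L)
  tt <- matrix(10L, 1L, 4L)
  ts <- make_tileset(m, tt, population = c("A", "A", "B", "B"))
  dd <- dmrTest(ts, "A", "B", min_individuals_per_group = 2L)
  expect_equal(dd$meth_diff, 80)
  expect_lte(dd$qvalue, 0.05)
  expect_identical(dd$call, "hyper")
  ## orientation: swapping the focal group flips the sign and the call
  dd2 <- dmrTest(ts, "B", "A", min_individuals_per_group = 2L)
  expect_equal(dd2$meth_diff, -80)
  expect_identical(dd2$call, "hypo")
  ## the pooled 18/2 vs 2/18 exact test agrees that this is significant
  expect_lte(fisher.test(matrix(c(18, 2, 2, 18), 2))$p.value, 0.05)
})

test_that("a 10-point difference is ns regardless of coverage depth", {
  m <- matrix(c(5000L, 5000L, 4000L, 4000L), 1L)
  tt <- matrix(10000L, 1L, 4L)
  ts <- make_tileset(m, tt, population = c("A", "A", "B", "B"))
  dd <- dmrTest(ts, "A", "B", min_individuals_per_group = 2L)
  expect_equal(dd$meth_diff, 10)
  expect_lt(dd$qvalue, 1e-6)            # overwhelmingly significant p
  expect_identical(dd$call, "ns")       # but below the 15-point rule
})

test_that("the closed-form LRT matches the binomial glm deviance test", {
  set.seed(42)
  n1 <- 6L; n2 <- 5L
  pop <- rep(c("A", "B"), c(n1, n2))
  m <- matrix(0L, 40L, n1 + n2); tt <- m
  for (i in seq_len(nrow(m))) {
    tot <- rpois(n1 + n2, 20) + 1L
    pr <- c(rep(runif(1, .2, .8), n1), rep(runif(1, .2, .8), n2))
    tt[i, ] <- tot
    m[i, ] <- rbinom(n1 + n2, tot, pr)
  }
  ts <- make_tileset(m, tt, population = pop)
  dd <- dmrTest(ts, "A", "B", min_individuals_per_group = 2L)
  for (i in seq_len(nrow(m))) {
    fit <- glm(cbind(m[i, ], tt[i, ] - m[i, ]) ~ factor(pop),
               family = binomial())
    p_glm <- anova(fit, test = "Chisq")$`Pr(>Chi)`[2]
    expect_equal(dd$pvalue[i], p_glm, tolerance = 1e-6)
  }
})

test_that("single-sample groups fall back to the exact pooled-count test", {
  m <- matrix(c(9L, 1L, 1L), 1L)
  tt <- matrix(10L, 1L, 3L)
  ts <- make_tileset(m, tt, population = c("A", "B", "B"))
  dd <- dmrTest(ts, "A", "B", min_individuals_per_group = 1L)
  want <- fisher.test(matrix(c(9, 1, 2, 18), 2, byrow = TRUE))$p.value
  expect_equal(dd$pvalue, want, tolerance = 1e-12)
})

test_that("BH adjustment matches a literal step-up oracle", {
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(5:60, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("tightening thresholds never adds DMRs", {
  set.seed(101)
  pop <- rep(c("A", "B"), each = 8L)
  fr <- matrix(runif(200 * 16, 0.2, 0.8), 200)
  cnt <- sample_counts(fr)
  ts <- make_tileset(cnt$meth, cnt$total, population = pop)
  base <- dmrTest(ts, "A", "B", diff_threshold = 10, q_threshold = 0.2)
  for (dt in c(15, 25)) for (qt in c(0.05, 0.01)) {
    tight <- dmrTest(ts, "A", "B", diff_threshold = dt, q_threshold = qt)
    expect_lte(sum(tight$call != "ns"), sum(base$call != "ns"))
    ## every tighter-threshold DMR is also a looser-threshold DMR
    expect_true(all(tight$tile[tight$call != "ns"] %in%
                      base$tile[base$call != "ns"]))
  }
})

test_that("clustering recovers a strong two-group structure", {
  set.seed(202)
  pop <- rep(c("A", "B"), each = 4L)
  ## group-specific tile profiles: high correlation within a group, none
  ## between groups
  base_a <- runif(50, 0.2, 0.8); base_b <- runif(50, 0.2, 0.8)
  fr <- cbind(matrix(base_a + rnorm(50 * 4, 0, 0.02), 50),
              matrix(base_b + rnorm(50 * 4, 0, 0.02), 50))
  cnt <- sample_counts(pmin(pmax(fr, 0), 1), mean_depth = 200)
  ts <- make_tileset(cnt$meth, cnt$total, population = pop)
  cl <- clusterAndProject(ts)
  cut2 <- cutree(cl$dendrogram, k = 2L)
  expect_equal(length(unique(cut2[1:4])), 1L)
  expect_equal(length(unique(cut2[5:8])), 1L)
  expect_false(cut2[1] == cut2[5])
  ## PC scores are invariant to tile order
  perm <- sample(nrow(ts))
  cl_perm <- clusterAndProject(ts[perm, ])
  expect_equal(abs(cl_perm$scores), abs(cl$scores), tolerance = 1e-8)
})

test_that("duplicated samples merge at distance zero; constant samples error", {
  set.seed(303)
  fr <- matrix(runif(30, 0.2, 0.8), 10L, 3L)
  fr <- cbind(fr, fr[, 1])                   # sample 4 duplicates sample 1
  cnt <- list(meth = matrix(as.integer(round(fr * 100)), 10L),
              total = matrix(100L, 10L, 4L))
  ts <- make_tileset(cnt$meth, cnt$total, population = rep("A", 4L))
  cl <- clusterAndProject(ts)
  dm <- as.matrix(cl$distance)
  expect_equal(dm[1, 4], 0, tolerance = 1e-12)
  expect_equal(cl$scores[1, ], cl$scores[4, ], tolerance = 1e-10)
  ## a constant sample has no defined correlation
  bad_m <- cnt$meth; bad_m[, 2] <- 50L
  ts_bad <- make_tileset(bad_m, cnt$total, population = rep("A", 4L))
  err <- tryCatch(clusterAndProject(ts_bad), error = identity)
  expect_match(conditionMessage(err), "ind02")
  expect_error(clusterAndProject(ts[, 1:2]), ">= 3 samples")
})
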