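## End-to-end orchestration: salinity -> F_ST -> tiles -> DMR (all pairwise
## comparisons plus the K=2 meta-population comparison) -> annotation ->
## divergence summary, behind one plain-text configuration.

.RUN_DEFAULTS <- list(
  min_reads = 10, tile = 100, step = 100, min_individuals = 8,
  diff_threshold = 15, q_threshold = 0.05,
  min_presence = 0.65, min_pops_passing = 2, min_maf = 0.05,
  grouping = "site", coverage_dialect = "zero_based",
  simulate = FALSE, seed = 1)

#' Read a run configuration
#'
#' Plain-text `key: value` format, one entry per line; `#` starts a comment.
#' Unknown keys are kept verbatim (paths etc.). Numeric-looking values are
#' converted; `true`/`false` become logicals. Defaults mirror the standard
#' thresholds: min_reads 10, tile 100, step 100, min_individuals 8,
#' diff_threshold 15, q_threshold 0.05, min_presence 0.65, min_maf 0.05.
#'
#' @param path config file path.
#' @return named list (class `epiDivergeConfig`).
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path))
    epiStop("epiDiverge_config_error", "config file not found: %s", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  bad <- vapply(kv, length, 0L) != 3L
  if (any(bad))
    epiStop("epiDiverge_config_error", "malformed config line: '%s'",
            lines[which(bad)[1L]])
  cfg <- .RUN_DEFAULTS
  for (m in kv) {
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <-
      if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
      else if (!is.na(num)) num
      else val
  }
  structure(cfg, class = "epiDivergeConfig")
}

.requireKeys <- function(config, keys) {
  missing <- keys[!vapply(keys, function(k) !is.null(config[[k]]), TRUE)]
  if (length(missing))
    epiStop("epiDiverge_config_error",
            "missing config key(s): %s", paste(missing, collapse = ", "))
}

#' Run the full divergence pipeline
#'
#' Executes every stage against the inputs named in `config` and writes
#' per-stage TSVs, a JSON divergence summary, and a plain-text report into
#' `config$outdir`. With `simulate: true`, synthetic inputs are generated
#' first (into `<outdir>/sim`) from the config seed, making the run fully
#' self-contained and deterministic.
#'
#' Config keys: `outdir` (required); either `simulate: true` or the input
#' paths `genotypes` (VCF or TSV), `popmap`, `coverage_dir`, `gff`; optional
#' `salinity_csv`; thresholds as in [readRunConfig()]; `grouping` (`site` or
#' `meta_population`) selects the population structure for F_ST and P_ST.
#'
#' @param config an `epiDivergeConfig` list (from [readRunConfig()]) or path.
#' @return Invisibly, a list with the summary and the paths of all outputs.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  .requireKeys(config, "outdir")
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- c(sprintf("epiDiverge run: %s", format(Sys.time(), "%Y-%m-%d")),
              "", "## Resolved configuration")
  report <- c(report, vapply(names(config), function(k)
    sprintf("  %s: %s", k, paste(format(config[[k]]), collapse = " ")), ""))
  paths <- list()

  if (isTRUE(config$simulate)) {
    simdir <- file.path(outdir, "sim")
    scfg <- simConfig(
      n_loci = as.integer(config$n_loci %||% 1567L),
      n_tiles = as.integer(config$n_tiles %||% 500L),
      n_individuals_per_pop = as.integer(config$n_individuals_per_pop %||% 20L),
      n_genes = as.integer(config$n_genes %||% 100L),
      genome_length = config$genome_length %||% 1e6,
      seed = as.integer(config$seed))
    simulateGenotypes(scfg, simdir)
    simulateMethylomes(scfg, file.path(simdir, "coverage"))
    simulateGenomeAnnotation(scfg, file.path(simdir, "annotation.gff3"))
    simulateSalinitySeries(c(LC = 22, LF = 18, SL = 12, VB = 4),
                           noise_sd = 3, n_days = 365L,
                           seed = as.integer(config$seed),
                           path = file.path(simdir, "salinity.csv"))
    config$genotypes <- file.path(simdir, "genotypes.vcf")
    config$popmap <- file.path(simdir, "popmap.tsv")
    config$coverage_dir <- file.path(simdir, "coverage")
    config$gff <- file.path(simdir, "annotation.gff3")
    config$salinity_csv <- file.path(simdir, "salinity.csv")
    report <- c(report, "", "## Stage 0: simulate",
                sprintf("  synthetic inputs written under %s", simdir))
  }
  .requireKeys(config, c("genotypes", "popmap", "coverage_dir", "gff"))
  for (k in c("genotypes", "popmap", "gff"))
    if (!file.exists(config[[k]]))
      epiStop("epiDiverge_config_error", "input '%s' not found: %s",
              k, config[[k]])
  popmap <- readPopMap(config$popmap)
  grouping <- config$grouping

  ## -- stage 1: salinity --------------------------------------------------
  report <- c(report, "", "## Stage 1: salinity")
  if (!is.null(config$salinity_csv)) {
    sal <- readSalinityCsv(config$salinity_csv)
    prof <- salinityProfiles(sal)
    paths$salinity <- writeTsv(prof, file.path(outdir, "salinity_profiles.tsv"))
    report <- c(report, sprintf("  %d site profile(s) -> %s",
                                nrow(prof), paths$salinity))
  } else {
    report <- c(report, "  no salinity_csv given; skipped")
  }

  ## -- stage 2: fst -------------------------------------------------------
  report <- c(report, "", "## Stage 2: fst")
  gm <- if (grepl("\\.vcf$", config$genotypes, ignore.case = TRUE))
    readGenotypesVcf(config$genotypes, popmap)
  else readGenotypeTsv(config$genotypes, popmap)
  gm <- filterLoci(gm, min_presence = config$min_presence,
                   min_pops_passing = config$min_pops_passing,
                   min_maf = config$min_maf)
  fst <- perLocusFst(gm, grouping = grouping)
  msum <- meanFst(fst)
  paths$fst <- writeTsv(fst, file.path(outdir, "per_locus_fst.tsv"))
  report <- c(report,
    sprintf("  %d loci after filters; mean theta = %.4f (ratio of sums %.4f)",
            nrow(fst), msum$mean_of_thetas, msum$ratio_of_sums))

  ## -- stage 3: tiles -----------------------------------------------------
  report <- c(report, "", "## Stage 3: tiles")
  cov_files <- list.files(config$coverage_dir, pattern = "\\.cov$",
                          full.names = TRUE)
  if (!length(cov_files))
    epiStop("epiDiverge_config_error", "no .cov files under %s",
            config$coverage_dir)
  covs <- lapply(cov_files, readBismarkCoverage,
                 dialect = config$coverage_dialect)
  covs <- lapply(covs, filterByCoverage, min_reads = config$min_reads)
  tiles <- makeTiles(covs, popmap, tile = config$tile, step = config$step,
                     min_individuals_per_group = config$min_individuals,
                     grouping = grouping)
  paths$tiles <- writeTilesTsv(tiles, file.path(outdir, "tiles.tsv"))
  report <- c(report, sprintf("  %d tiles x %d samples pass filters",
                              nrow(tiles), ncol(tiles)))

  ## -- stage 4: dmr -------------------------------------------------------
  report <- c(report, "", "## Stage 4: dmr")
  pops <- sort(unique(popmap[[grouping]]))
  comparisons <- utils::combn(pops, 2L, simplify = FALSE)
  dmr_all <- list()
  for (cmp in comparisons) {
    dd <- dmrTest(tiles, cmp[1], cmp[2],
                  diff_threshold = config$diff_threshold,
                  q_threshold = config$q_threshold,
                  min_individuals_per_group = config$min_individuals)
    dd$comparison <- paste(cmp[1], cmp[2], sep = "_vs_")
    dmr_all[[length(dmr_all) + 1L]] <- dd
    report <- c(report, sprintf("  %s: %d tiles tested, %d DMRs",
                                dd$comparison[1] %||% "", nrow(dd),
                                sum(dd$call != "ns")))
  }
  if (length(unique(popmap$meta_population)) == 2L &&
      grouping != "meta_population") {
    meta_tiles <- makeTiles(covs, popmap, tile = config$tile,
                            step = config$step,
                            min_individuals_per_group = config$min_individuals,
                            grouping = "meta_population")
    metas <- sort(unique(popmap$meta_population))
    dd <- dmrTest(meta_tiles, metas[1], metas[2],
                  diff_threshold = config$diff_threshold,
                  q_threshold = config$q_threshold,
                  min_individuals_per_group = config$min_individuals)
    dd$comparison <- paste0("K2_", metas[1], "_vs_", metas[2])
    dmr_all[[length(dmr_all) + 1L]] <- dd
    report <- c(report, sprintf("  %s: %d tiles tested, %d DMRs",
                                dd$comparison[1] %||% "", nrow(dd),
                                sum(dd$call != "ns")))
  }
  dmrs <- do.call(rbind, dmr_all)
  paths$dmrs <- writeTsv(dmrs, file.path(outdir, "dmrs.tsv"))

  ## -- stage 5: annotate --------------------------------------------------
  report <- c(report, "", "## Stage 5: annotate")
  model <- buildFeatureModel(config$gff)
  cls <- classifyRegions(tiles, model)
  paths$classified <- writeTsv(cls, file.path(outdir, "tile_features.tsv"))
  obs_dist <- featureDistribution(cls$category)
  rnd <- generateRandomTiles(model,
                             n_per_set = as.integer(config$random_n %||% 2000L),
                             n_sets = as.integer(config$random_sets %||% 6L),
                             seed = as.integer(config$seed))
  rnd_dist <- rowMeans(vapply(rnd, function(g)
    featureDistribution(classifyRegions(g, model)$category),
    numeric(length(obs_dist))))
  ksr <- compareFeatureDistributions(obs_dist, rnd_dist,
                                     n2 = as.integer(config$random_n %||% 2000L))
  dist_tab <- data.frame(category = names(obs_dist),
                         observed = as.numeric(obs_dist),
                         random = as.numeric(rnd_dist))
  paths$feature_dist <- writeTsv(dist_tab,
                                 file.path(outdir, "feature_distributions.tsv"))
  report <- c(report,
    sprintf("  observed vs random feature distribution: KS D = %.3f, p = %.3f",
            ksr$D, ksr$p_value))

  ## -- stage 6: divergence ------------------------------------------------
  report <- c(report, "", "## Stage 6: divergence")
  pst <- pstTiles(tiles, grouping = grouping)
  paths$pst <- writeTsv(pst, file.path(outdir, "tile_pst.tsv"))
  gfst <- geneFst(fst, model)
  paths$gene_fst <- writeTsv(gfst, file.path(outdir, "gene_fst.tsv"))
  agg <- aggregateByGene(tiles, pst, model, gfst, dmrs = dmrs)
  paths$gene_join <- writeTsv(agg$joint, file.path(outdir, "gene_join.tsv"))
  summ <- divergenceSummary(agg$joint, tile_pst = pst)
  summ$mean_fst_loci <- msum$mean_of_thetas
  paths$summary <- file.path(outdir, "divergence_summary.json")
  jsonlite::write_json(summ, paths$summary, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  report <- c(report,
    sprintf("  mean P_ST (tiles) = %.4f; mean F_ST (loci) = %.4f; ratio = %.2f",
            summ$mean_pst_tiles, summ$mean_fst_loci,
            summ$mean_pst_tiles / summ$mean_fst_loci),
    sprintf("  joint gene table: %d genes (%d methylation-only, %d SNP-only)",
            nrow(agg$joint), length(agg$meth_only), length(agg$fst_only)))

  paths$report <- file.path(outdir, "report.txt")
  writeLines(report, paths$report)
  invisible(list(summary = summ, mean_fst = msum, paths = paths,
                 report = report))
}
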