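## Synthetic-data generators. These emulate the statistical structure of a
## four-population reduced-representation study (RAD-style genotypes plus
## RRBS-style CpG coverage) so the downstream estimators can be validated
## against known truth. All generators are deterministic given the config
## seed and emit the same standard formats the pipeline readers consume.

.siteNames <- function(k) {
  if (k == 4L) c("LC", "LF", "SL", "VB") else sprintf("P%d", seq_len(k))
}

## K=2 meta-population grouping mirroring the study's structure result:
## sites 1+3 vs 2+4 for k=4 (LC+SL vs LF+VB), else first half vs second half.
.metaOf <- function(site, sites) {
  k <- length(sites)
  grp1 <- if (k == 4L) sites[c(1L, 3L)] else sites[seq_len(ceiling(k / 2))]
  ifelse(site %in% grp1, "pop1", "pop2")
}

.makePopmap <- function(config) {
  sites <- .siteNames(config@n_populations)
  n <- config@n_individuals_per_pop
  individual <- unlist(lapply(sites, function(s) sprintf("%s_%02d", s, seq_len(n))))
  site <- rep(sites, each = n)
  data.frame(individual = individual, site = site,
             meta_population = .metaOf(site, sites),
             stringsAsFactors = FALSE)
}

#' Simulate genotypes under a Balding--Nichols divergence model
#'
#' Draws, per locus, an ancestral allele frequency `p ~ Uniform(range)`, then
#' per-population frequencies from `Beta(p(1-F)/F, (1-p)(1-F)/F)` — the
#' Balding--Nichols model, whose single parameter `F` equals the expected
#' Weir--Cockerham theta — and diploid dosages `Binomial(2, p_pop)`.
#' Genotype calls are masked missing at `missing_rate`. Files written:
#' `genotypes.vcf`, `genotypes.tsv` (rows = loci, columns = individuals,
#' codes 0/1/2/NA) and `popmap.tsv`.
#'
#' @param config a [SimConfig-class].
#' @param outdir output directory (created if needed); `NULL` skips writing.
#' @return Invisibly, a list with the [GenotypeMatrix-class] and the paths of
#'   any files written.
#' @examples
#' cfg <- simConfig(n_loci = 50L, n_individuals_per_pop = 5L, seed = 3L)
#' gm <- simulateGenotypes(cfg)$genotypes
#' gm
#' @export
simulateGenotypes <- function(config, outdir = NULL) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (config@n_populations < 2L)
    epiStop("epiDiverge_config_error",
            "at least 2 populations are required (got %d)", config@n_populations)
  set.seed(deriveSeed(config@seed, 1L))
  popmap <- .makePopmap(config)
  L <- config@n_loci
  k <- config@n_populations
  n <- config@n_individuals_per_pop
  FF <- config@divergence_F

  p_anc <- runif(L, config@ancestral_freq_range[1], config@ancestral_freq_range[2])
  shape <- (1 - FF) / FF
  p_pop <- matrix(rbeta(L * k, rep(p_anc, k) * shape,
                        rep(1 - p_anc, k) * shape), nrow = L)
  calls <- matrix(NA_integer_, L, k * n)
  for (j in seq_len(k)) {
    cols <- ((j - 1L) * n + 1L):(j * n)
    calls[, cols] <- rbinom(L * n, 2L, rep(p_pop[, j], n))
  }
  if (config@missing_rate > 0) {
    calls[runif(length(calls)) < config@missing_rate] <- NA_integer_
  }
  pos <- sort(sample.int(as.integer(config@genome_length), L))
  loci <- data.frame(locus_id = sprintf("snp%05d", seq_len(L)),
                     chrom = "chr1", pos = pos,
                     radlocus = sprintf("rad%05d", seq_len(L)),
                     stringsAsFactors = FALSE)
  gm <- GenotypeMatrix(calls, loci, popmap)

  paths <- list()
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths$vcf <- writeGenotypesVcf(gm, file.path(outdir, "genotypes.vcf"))
    paths$tsv <- writeGenotypeTsv(gm, file.path(outdir, "genotypes.tsv"))
    paths$popmap <- writePopMap(popmap, file.path(outdir, "popmap.tsv"))
  }
  invisible(list(genotypes = gm, paths = paths))
}

#' Simulate per-individual CpG methylomes over 100-bp tiles
#'
#' Hierarchical model on the methylation-fraction scale: per tile a base mean
#' `mu ~ Uniform(base_mean_range)`; per population an offset
#' `Normal(0, sigma_between)`; per individual a true fraction
#' `Normal(population mean, sigma_within)` truncated to \[0, 1\]. Read counts:
#' per CpG, depth `Poisson(mean_read_depth)` and methylated reads
#' `Binomial(depth, fraction)`. One bismark-coverage TSV (zero-based dialect)
#' is written per individual when `outdir` is given.
#'
#' A warning is raised when more than 10% of individual fractions at any tile
#' fall outside \[0, 1\] before truncation, since truncation then distorts the
#' variance structure the P_ST calibration relies on.
#'
#' @param config a [SimConfig-class].
#' @param outdir output directory, or `NULL` to skip file output.
#' @return Invisibly, a list with `fractions` (tiles x individuals matrix of
#'   true latent fractions), `tiles` (a `GRanges`), `popmap`, and `paths`.
#' @export
simulateMethylomes <- function(config, outdir = NULL) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (config@cpgs_per_tile < 1L || config@mean_read_depth < 1)
    epiStop("epiDiverge_config_error",
            "cpgs_per_tile and mean_read_depth must be >= 1")
  set.seed(deriveSeed(config@seed, 2L))
  popmap <- .makePopmap(config)
  fr <- simulateTileFractions(config, new_seed = FALSE)
  Tn <- config@n_tiles
  N <- nrow(popmap)
  cpt <- config@cpgs_per_tile
  ts <- config@tile_size

  ## CpG positions: fixed, evenly spread within each tile (0-based)
  off <- floor((seq_len(cpt) - 0.5) / cpt * ts)
  tile0 <- (seq_len(Tn) - 1L) * ts
  pos0 <- as.vector(outer(off, tile0, "+"))      # cpt * Tn positions, 0-based
  ord <- order(pos0)
  pos0 <- pos0[ord]

  depth <- matrix(rpois(Tn * cpt * N, config@mean_read_depth), nrow = Tn * cpt)
  frac_cpg <- fr[rep(seq_len(Tn), each = cpt), , drop = FALSE]
  meth <- matrix(rbinom(length(depth), as.vector(depth), as.vector(frac_cpg)),
                 nrow = Tn * cpt)
  depth <- depth[ord, , drop = FALSE]
  meth <- meth[ord, , drop = FALSE]

  paths <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- vapply(seq_len(N), function(i) {
      keep <- depth[, i] > 0                     # bismark omits uncovered sites
      m <- meth[keep, i]; tt <- depth[keep, i]
      df <- data.frame(chrom = "chr1", start = pos0[keep],
                       end = pos0[keep] + 1L,
                       pct = sprintf("%.6g", 100 * m / tt),
                       meth = m, unmeth = tt - m)
      path <- file.path(outdir, paste0(popmap$individual[i], ".cov"))
      write.table(df, path, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
      path
    }, character(1))
    names(paths) <- popmap$individual
  }
  tiles <- GRanges("chr1", IRanges(tile0 + 1L, tile0 + ts))
  invisible(list(fractions = fr, tiles = tiles, popmap = popmap,
                 paths = paths))
}

#' Simulate the latent tile-level methylation fractions only
#'
#' The fraction layer of [simulateMethylomes()] without read-count sampling:
#' useful for validating the P_ST variance partition against its design value
#' free of binomial measurement noise.
#'
#' @param config a [SimConfig-class].
#' @param new_seed reset the RNG from the config seed (set `FALSE` when called
#'   from within another generator).
#' @return Numeric matrix of true fractions, tiles x individuals, with
#'   individual ids as column names.
#' @export
simulateTileFractions <- function(config, new_seed = TRUE) {
  stopifnot(is(config, "SimConfig"))
  if (new_seed) set.seed(deriveSeed(config@seed, 2L))
  popmap <- .makePopmap(config)
  Tn <- config@n_tiles
  k <- config@n_populations
  n <- config@n_individuals_per_pop

  mu <- runif(Tn, config@base_mean_range[1], config@base_mean_range[2])
  popmean <- mu + matrix(rnorm(Tn * k, 0, config@sigma_between), nrow = Tn)
  fr <- matrix(NA_real_, Tn, k * n)
  for (j in seq_len(k)) {
    cols <- ((j - 1L) * n + 1L):(j * n)
    fr[, cols] <- rnorm(Tn * n, rep(popmean[, j], n), config@sigma_within)
  }
  out_mass <- rowMeans(fr < 0 | fr > 1)
  if (any(out_mass > 0.10)) {
    warning(sprintf(paste0("%d tile(s) have > 10%% of individual fractions ",
                           "truncated to [0,1]; variance structure is ",
                           "distorted there"), sum(out_mass > 0.10)))
  }
  fr[fr < 0] <- 0
  fr[fr > 1] <- 1
  colnames(fr) <- popmap$individual
  rownames(fr) <- sprintf("tile%05d", seq_len(Tn))
  fr
}

#' Simulate a GFF3 gene-model annotation
#'
#' Places `n_genes` non-overlapping genes on alternating strands along a
#' single chromosome, each with a 5'UTR, 1--3 exons with intervening introns,
#' and a 3'UTR. Coordinates are valid 1-based inclusive GFF3; gene IDs are
#' stable (`gene00001`, ...). Gaps between genes are randomized so a sizeable
#' intergenic fraction remains.
#'
#' @param config a [SimConfig-class].
#' @param path output GFF3 path, or `NULL` to return lines invisibly.
#' @return Invisibly, the GFF3 text lines (and writes `path` when given).
#' @export
simulateGenomeAnnotation <- function(config, path = NULL) {
  stopifnot(is(config, "SimConfig"))
  set.seed(deriveSeed(config@seed, 3L))
  G <- as.integer(config@genome_length)
  ng <- config@n_genes

  lines <- c("##gff-version 3",
             sprintf("##sequence-region chr1 1 %d", G))
  if (ng > 0L) {
    n_ex <- sample(1:3, ng, replace = TRUE)
    utr5 <- sample(100:200, ng, replace = TRUE)
    utr3 <- sample(150:250, ng, replace = TRUE)
    ex_len <- lapply(seq_len(ng), function(i) sample(150:300, n_ex[i], replace = TRUE))
    in_len <- lapply(seq_len(ng), function(i)
      if (n_ex[i] > 1L) sample(200:400, n_ex[i] - 1L, replace = TRUE) else integer(0))
    span <- utr5 + utr3 + vapply(ex_len, sum, 0L) + vapply(in_len, sum, 0L)
    slack <- G - sum(span) - 2L * ng   # >= 1-bp gaps guaranteed below
    if (slack <= 0L)
      epiStop("epiDiverge_config_error",
              "cannot pack %d genes (total span %d bp) into %d bp", ng, sum(span), G)
    gaps <- as.vector(stats::rmultinom(1, slack, rep(1, ng + 1L)))
    starts <- integer(ng)
    cursor <- 1L
    for (i in seq_len(ng)) {
      cursor <- cursor + gaps[i] + 1L
      starts[i] <- cursor
      cursor <- cursor + span[i] + 1L
    }
    strands <- rep(c("+", "-"), length.out = ng)

    for (i in seq_len(ng)) {
      gid <- sprintf("gene%05d", i)
      gstart <- starts[i]; gend <- gstart + span[i] - 1L
      ## build blocks 5'->3' in transcription order, then map to genome coords
      blocks <- list(c("five_prime_UTR", utr5[i]))
      for (e in seq_len(n_ex[i])) {
        blocks <- c(blocks, list(c("exon", ex_len[[i]][e])))
        if (e < n_ex[i]) blocks <- c(blocks, list(c("intron", in_len[[i]][e])))
      }
      blocks <- c(blocks, list(c("three_prime_UTR", utr3[i])))
      lens <- as.integer(vapply(blocks, function(b) b[2], ""))
      types <- vapply(blocks, function(b) b[1], "")
      if (strands[i] == "-") { lens <- rev(lens); types <- rev(types) }
      ends <- gstart + cumsum(lens) - 1L
      bstarts <- c(gstart, ends[-length(ends)] + 1L)

      lines <- c(lines,
        sprintf("chr1\tepiDiverge\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                gstart, gend, strands[i], gid),
        sprintf("chr1\tepiDiverge\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                gstart, gend, strands[i], gid, gid))
      keep <- types != "intron"            # introns are implied, per GFF3 usage
      ## UTR sequence is exonic: emit exon rows covering UTRs too
      exon_rows <- which(keep)
      for (b in exon_rows) {
        lines <- c(lines,
          sprintf("chr1\tepiDiverge\t%s\t%d\t%d\t.\t%s\t.\tID=%s.%s.%d;Parent=%s.t1",
                  types[b], bstarts[b], ends[b], strands[i], gid, types[b], b, gid))
        if (types[b] != "exon") {
          lines <- c(lines,
            sprintf("chr1\tepiDiverge\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon.%d;Parent=%s.t1",
                    bstarts[b], ends[b], strands[i], gid, b, gid))
        }
      }
    }
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Simulate daily salinity series
#'
#' Daily values are the site mean plus Gaussian noise, floored at 0 psu.
#'
#' @param site_means named numeric vector of site mean salinities (psu).
#' @param noise_sd SD of daily Gaussian noise (psu).
#' @param n_days number of days (>= 10).
#' @param seed integer seed.
#' @param start_date first day (ISO-8601).
#' @param path output CSV path (`site,date,psu`), or `NULL`.
#' @return Invisibly, the long-format data.frame.
#' @export
simulateSalinitySeries <- function(site_means, noise_sd = 2, n_days = 365L,
                                   seed = 1L, start_date = "2015-01-01",
                                   path = NULL) {
  if (n_days < 10L)
    epiStop("epiDiverge_config_error", "n_days must be >= 10 (got %d)", n_days)
  set.seed(deriveSeed(seed, 4L))
  if (is.null(names(site_means)))
    names(site_means) <- sprintf("site%d", seq_along(site_means))
  dates <- as.Date(start_date) + seq_len(n_days) - 1L
  out <- do.call(rbind, lapply(names(site_means), function(s) {
    psu <- pmax(0, site_means[[s]] + rnorm(n_days, 0, noise_sd))
    data.frame(site = s, date = format(dates, "%Y-%m-%d"),
               psu = round(psu, 3), stringsAsFactors = FALSE)
  }))
  if (!is.null(path))
    write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(out)
}
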