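## Genome tiling of CpG counts: fixed 100-bp non-overlapping windows anchored
## at coordinate 0 of each chromosome (step = tile width).

#' Pool CpG counts into fixed-width tiles
#'
#' Sums each individual's (methylated, unmethylated) CpG counts within
#' non-overlapping `tile`-bp windows anchored at position 0 of every
#' chromosome. A tile is retained only when, in every group of `groups`, at
#' least `min_individuals_per_group` individuals have at least one read in
#' the tile ("covered"). Counts are conserved: for each individual, the sum
#' over a chromosome's tiles equals the sum over its CpGs.
#'
#' @param covs list of [CpGCoverage-class] objects (typically already passed
#'   through [filterByCoverage()]).
#' @param popmap population map data.frame aligning `individual` with a
#'   grouping column.
#' @param tile tile width in bp (default 100).
#' @param step step size in bp; must equal `tile` (non-overlapping tiling).
#' @param min_individuals_per_group occupancy rule (default 8); use 0 to keep
#'   every tile.
#' @param grouping name of the popmap column defining the groups (default
#'   `"site"`).
#' @return A [MethylTileSet-class].
#' @export
makeTiles <- function(covs, popmap, tile = 100L, step = 100L,
                      min_individuals_per_group = 8L, grouping = "site") {
  if (tile != step)
    epiStop("epiDiverge_tiling_error",
            "only non-overlapping tiling is supported (tile == step)")
  ids <- vapply(covs, individualId, character(1))
  names(covs) <- ids
  missing_ind <- setdiff(popmap$individual, ids)
  if (length(missing_ind))
    epiStop("epiDiverge_popmap_error",
            "no coverage for individuals: %s", paste(missing_ind, collapse = ", "))
  covs <- covs[popmap$individual]
  groups <- factor(popmap[[grouping]])
  small <- table(groups) < min_individuals_per_group
  if (any(small))
    epiStop("epiDiverge_tiling_error",
            "group(s) smaller than the occupancy threshold %d: %s",
            min_individuals_per_group,
            paste(names(which(small)), collapse = ", "))

  ## per-individual tile totals keyed by chrom:tile_start (0-based)
  keyed <- lapply(covs, function(cv) {
    s <- cpgSites(cv)
    if (!length(s)) return(NULL)
    t0 <- (start(s) - 1L) %/% tile * tile
    key <- paste0(seqnames(s), ":", t0)
    data.frame(key = key,
               meth = mcols(s)$meth,
               total = mcols(s)$meth + mcols(s)$unmeth,
               stringsAsFactors = FALSE)
  })
  all_keys <- sort(unique(unlist(lapply(keyed, function(d) d$key))))
  if (!length(all_keys)) {
    se <- SummarizedExperiment(
      assays = list(meth = matrix(0L, 0, length(covs)),
                    total = matrix(0L, 0, length(covs))),
      rowRanges = GRanges(),
      colData = DataFrame(popmap, row.names = popmap$individual))
    colData(se)$population <- popmap[[grouping]]
    return(new("MethylTileSet", se))
  }
  meth <- total <- matrix(0L, length(all_keys), length(covs),
                          dimnames = list(all_keys, names(covs)))
  for (i in seq_along(keyed)) {
    d <- keyed[[i]]
    if (is.null(d)) next
    mm <- tapply(d$meth, d$key, sum)
    tt <- tapply(d$total, d$key, sum)
    meth[names(mm), i] <- as.integer(mm)
    total[names(tt), i] <- as.integer(tt)
  }
  if (min_individuals_per_group > 0L) {
    covered <- (total > 0) %*% groupIndicator(groups)
    keep <- rowSums(covered < min_individuals_per_group) == 0L
    meth <- meth[keep, , drop = FALSE]
    total <- total[keep, , drop = FALSE]
    all_keys <- all_keys[keep]
  }
  chrom <- sub(":.*$", "", all_keys)
  t0 <- as.integer(sub("^.*:", "", all_keys))
  rr <- GRanges(chrom, IRanges(t0 + 1L, t0 + tile))
  names(rr) <- all_keys
  cd <- DataFrame(popmap, row.names = popmap$individual)
  cd$population <- popmap[[grouping]]
  se <- SummarizedExperiment(assays = list(meth = meth, total = total),
                             rowRanges = rr, colData = cd)
  new("MethylTileSet", sort(se))
}

#' Re-apply the tile occupancy rule for a (sub)grouping
#'
#' Subsets a [MethylTileSet-class] to the samples of the groups named in
#' `keep_groups` (default: all) and keeps the tiles covered by at least
#' `min_individuals_per_group` individuals in every retained group. Used to
#' restrict an all-sites tile set to one pairwise comparison.
#'
#' @param tiles a [MethylTileSet-class].
#' @param grouping colData column name or factor.
#' @param keep_groups group levels to retain (default all).
#' @param min_individuals_per_group occupancy threshold (default 8).
#' @return The subset [MethylTileSet-class].
#' @export
occupancyFilter <- function(tiles, grouping = "population", keep_groups = NULL,
                            min_individuals_per_group = 8L) {
  stopifnot(is(tiles, "MethylTileSet"))
  groups <- resolveGrouping(tiles, grouping)
  if (!is.null(keep_groups)) {
    sel <- groups %in% keep_groups
    tiles <- tiles[, sel]
    groups <- droplevels(groups[sel])
  }
  covered <- (assay(tiles, "total") > 0) %*% groupIndicator(groups)
  keep <- rowSums(covered < min_individuals_per_group) == 0L
  tiles[keep, ]
}

#' Read and write tile sets as TSV
#'
#' One row per tile with 0-based half-open coordinates (matching the
#' coverage-file convention) and per-individual `meth.<id>` / `total.<id>`
#' columns; `readTilesTsv` inverts `writeTilesTsv` so a run can re-enter the
#' pipeline from its intermediate files.
#'
#' @param path TSV path.
#' @param popmap population map (data.frame or path) restoring the grouping.
#' @return `readTilesTsv`: a [MethylTileSet-class].
#' @export
readTilesTsv <- function(path, popmap) {
  if (!file.exists(path))
    epiStop("epiDiverge_io_error", "tile TSV not found: %s", path)
  if (is.character(popmap)) popmap <- readPopMap(popmap)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  mcolsx <- grep("^meth\\.", colnames(df), value = TRUE)
  ids <- sub("^meth\\.", "", mcolsx)
  missing_ind <- setdiff(popmap$individual, ids)
  if (length(missing_ind))
    epiStop("epiDiverge_popmap_error",
            "individuals in population map absent from tile TSV: %s",
            paste(missing_ind, collapse = ", "))
  meth <- as.matrix(df[, paste0("meth.", popmap$individual), drop = FALSE])
  total <- as.matrix(df[, paste0("total.", popmap$individual), drop = FALSE])
  storage.mode(meth) <- "integer"; storage.mode(total) <- "integer"
  colnames(meth) <- colnames(total) <- popmap$individual
  rr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
  names(rr) <- paste0(df$chrom, ":", df$start)
  cd <- DataFrame(popmap, row.names = popmap$individual)
  cd$population <- popmap$site
  se <- SummarizedExperiment(assays = list(meth = meth, total = total),
                             rowRanges = rr, colData = cd)
  new("MethylTileSet", se)
}

#' @rdname readTilesTsv
#' @param tiles a [MethylTileSet-class].
#' @return `writeTilesTsv`: the path, invisibly.
#' @export
writeTilesTsv <- function(tiles, path) {
  stopifnot(is(tiles, "MethylTileSet"))
  rr <- rowRanges(tiles)
  df <- data.frame(chrom = as.character(seqnames(rr)),
                   start = start(rr) - 1L, end = end(rr))
  m <- assay(tiles, "meth"); tt <- assay(tiles, "total")
  colnames(m) <- paste0("meth.", colnames(m))
  colnames(tt) <- paste0("total.", colnames(tt))
  writeTsv(cbind(df, as.data.frame(m), as.data.frame(tt)), path)
}
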