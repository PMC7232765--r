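## Readers and writers for genotype matrices and population maps.
## VCF parsing is delegated to vcfR; writing uses a minimal GT-only VCF 4.2.

#' Read and write population maps
#'
#' A population map is a three-column TSV: `individual`, `site`,
#' `meta_population` (the latter optional on read; defaults to `site`).
#'
#' @param path TSV path.
#' @return `readPopMap`: a data.frame with the three columns.
#' @export
readPopMap <- function(path) {
  if (!file.exists(path))
    epiStop("epiDiverge_io_error", "population map not found: %s", path)
  pm <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("individual", "site") %in% colnames(pm)))
    epiStop("epiDiverge_io_error",
            "population map needs columns 'individual' and 'site': %s", path)
  if (!"meta_population" %in% colnames(pm)) pm$meta_population <- pm$site
  pm
}

#' @rdname readPopMap
#' @param popmap a population-map data.frame.
#' @export
writePopMap <- function(popmap, path) {
  writeTsv(popmap[, c("individual", "site", "meta_population")], path)
}

#' Read and write genotype-matrix TSV
#'
#' Layout: columns `locus_id`, `chrom`, `pos`, `radlocus`, then one column per
#' individual holding dosages 0/1/2 or NA.
#'
#' @param path TSV path.
#' @param popmap population map (data.frame or path) aligning individuals.
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypeTsv <- function(path, popmap) {
  if (!file.exists(path))
    epiStop("epiDiverge_io_error", "genotype TSV not found: %s", path)
  if (is.character(popmap)) popmap <- readPopMap(popmap)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  meta_cols <- c("locus_id", "chrom", "pos", "radlocus")
  if (!all(meta_cols %in% colnames(df)))
    epiStop("epiDiverge_io_error",
            "genotype TSV needs columns %s", paste(meta_cols, collapse = ", "))
  inds <- setdiff(colnames(df), meta_cols)
  missing_ind <- setdiff(popmap$individual, inds)
  if (length(missing_ind))
    epiStop("epiDiverge_popmap_error",
            "individuals in population map absent from genotypes: %s",
            paste(missing_ind, collapse = ", "))
  calls <- as.matrix(df[, popmap$individual, drop = FALSE])
  GenotypeMatrix(calls, df[, meta_cols], popmap)
}

#' @rdname readGenotypeTsv
#' @param gm a [GenotypeMatrix-class].
#' @export
writeGenotypeTsv <- function(gm, path) {
  stopifnot(is(gm, "GenotypeMatrix"))
  df <- cbind(lociInfo(gm)[, c("locus_id", "chrom", "pos", "radlocus")],
              as.data.frame(genotypeCalls(gm)))
  writeTsv(df, path)
}

#' Read genotypes from VCF
#'
#' Parses a VCF (via \pkg{vcfR}) into a [GenotypeMatrix-class], converting GT
#' fields to alternate-allele dosages. Multiallelic records are dropped with a
#' warning. The RAD-locus id is taken from the ID column prefix before the
#' first `:` when present, else the ID itself.
#'
#' @param path VCF path.
#' @param popmap population map (data.frame or path).
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypesVcf <- function(path, popmap) {
  if (!file.exists(path))
    epiStop("epiDiverge_io_error", "VCF not found: %s", path)
  if (is.character(popmap)) popmap <- readPopMap(popmap)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  biall <- !grepl(",", fix$ALT %||% "")
  if (!all(biall)) {
    warning(sum(!biall), " multiallelic record(s) dropped")
    v <- v[biall, ]
    fix <- fix[biall, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dose[clean == "0/0"] <- 0L
  dose[clean %in% c("0/1", "1/0")] <- 1L
  dose[clean == "1/1"] <- 2L
  missing_ind <- setdiff(popmap$individual, colnames(dose))
  if (length(missing_ind))
    epiStop("epiDiverge_popmap_error",
            "individuals in population map absent from VCF: %s",
            paste(missing_ind, collapse = ", "))
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- sprintf("snp%05d", which(is.na(ids) | ids == "."))
  has_rad <- grepl(":", ids)
  loci <- data.frame(locus_id = ifelse(has_rad, sub("^[^:]*:", "", ids), ids),
                     chrom = fix$CHROM,
                     pos = as.integer(fix$POS),
                     radlocus = sub(":.*$", "", ids),
                     stringsAsFactors = FALSE)
  GenotypeMatrix(dose[, popmap$individual, drop = FALSE], loci, popmap)
}

#' @rdname readGenotypesVcf
#' @param gm a [GenotypeMatrix-class].
#' @export
writeGenotypesVcf <- function(gm, path) {
  stopifnot(is(gm, "GenotypeMatrix"))
  calls <- genotypeCalls(gm)
  loci <- lociInfo(gm)
  gtcode <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(calls), ncol(calls))
  ok <- !is.na(calls)
  gt[ok] <- gtcode[calls[ok] + 1L]
  header <- c("##fileformat=VCFv4.2",
              "##source=epiDiverge",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(calls)), collapse = "\t"))
  ids <- ifelse(loci$radlocus == loci$locus_id, loci$locus_id,
                paste(loci$radlocus, loci$locus_id, sep = ":"))
  body <- paste(loci$chrom, loci$pos, ids, "A", "G", ".", "PASS",
                ".", "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
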