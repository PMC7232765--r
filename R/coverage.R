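## bismark coverage-file parsing and the per-CpG depth filter.

#' Read a bismark coverage file
#'
#' Parses the 6-column coverage TSV (chrom, start, end, percent methylation,
#' count methylated, count unmethylated). The percent column is ignored and
#' recomputed from counts downstream. Positions are normalized internally to
#' 1-based: the `zero_based` dialect (extraction with `--zero_based`) has
#' 0-based starts, the `one_based` dialect prints the position directly.
#'
#' @param path coverage file path.
#' @param individual sample id (default: file name without extension).
#' @param dialect `"zero_based"` (default) or `"one_based"`.
#' @return A [CpGCoverage-class]; empty files yield an empty object with a
#'   warning.
#' @export
readBismarkCoverage <- function(path, individual = NULL,
                                dialect = c("zero_based", "one_based")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    epiStop("epiDiverge_io_error", "coverage file not found: %s", path)
  individual <- individual %||% sub("\\.[^.]*$", "", basename(path))
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  if (!length(raw)) {
    warning("empty coverage file: ", path)
    return(new("CpGCoverage", individual = individual,
               sites = GRanges(meth = integer(0), unmeth = integer(0))))
  }
  parts <- strsplit(raw, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 6L))
    epiStop("epiDiverge_parse_error",
            "malformed coverage line %d in %s: expected 6 tab-separated fields, got %d",
            which(nfield != 6L)[1L], path, nfield[which(nfield != 6L)[1L]])
  m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  meth <- suppressWarnings(as.integer(m[, 5]))
  unmeth <- suppressWarnings(as.integer(m[, 6]))
  bad <- which(is.na(start) | is.na(meth) | is.na(unmeth))
  if (length(bad))
    epiStop("epiDiverge_parse_error",
            "malformed coverage line %d in %s: non-numeric field", bad[1L], path)
  if (any(meth < 0) || any(unmeth < 0))
    epiStop("epiDiverge_parse_error",
            "negative read count at line %d in %s",
            which(meth < 0 | unmeth < 0)[1L], path)
  pos1 <- if (dialect == "zero_based") start + 1L else start
  sites <- GRanges(m[, 1], IRanges(pos1, width = 1L),
                   meth = meth, unmeth = unmeth)
  o <- order(seqnames(sites), start(sites))
  new("CpGCoverage", individual = individual, sites = sites[o])
}

#' Filter CpGs by read depth
#'
#' Drops CpG sites whose total read count (methylated + unmethylated) is
#' below `min_reads`. The boundary is inclusive: a site with exactly
#' `min_reads` reads is kept.
#'
#' @param cov a [CpGCoverage-class].
#' @param min_reads minimum total reads per CpG (default 10).
#' @return The filtered [CpGCoverage-class].
#' @export
filterByCoverage <- function(cov, min_reads = 10L) {
  stopifnot(is(cov, "CpGCoverage"))
  s <- cpgSites(cov)
  keep <- (mcols(s)$meth + mcols(s)$unmeth) >= min_reads
  new("CpGCoverage", individual = individualId(cov), sites = s[keep])
}
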