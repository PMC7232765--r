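## Fixture builders shared across test files. Everything is generated in
## code; nothing is read from static data files.

## Write bismark-coverage lines (already-formatted strings) to a temp file.
write_cov <- function(lines, path = tempfile(fileext = ".cov")) {
  writeLines(lines, path)
  path
}

## A coverage line in the zero_based dialect.
cov_line <- function(chrom, start0, meth, unmeth) {
  pct <- if (meth + unmeth > 0) 100 * meth / (meth + unmeth) else 0
  sprintf("%s\t%d\t%d\t%s\t%d\t%d", chrom, start0, start0 + 1L,
          format(pct), meth, unmeth)
}

## Build a MethylTileSet directly from count matrices.
make_tileset <- function(meth, total, population,
                         chrom = "chr1", tile = 100L) {
  n <- nrow(meth)
  ids <- colnames(meth) %||% sprintf("ind%02d", seq_len(ncol(meth)))
  rr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = (seq_len(n) - 1L) * tile + 1L,
                            width = tile))
  names(rr) <- sprintf("%s:%d", chrom, (seq_len(n) - 1L) * tile)
  cd <- S4Vectors::DataFrame(individual = ids, population = population,
                             row.names = ids)
  colnames(meth) <- colnames(total) <- ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(meth = meth, total = total), rowRanges = rr, colData = cd)
  new("MethylTileSet", se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Sample binomial read counts for a fraction matrix (tiles x individuals).
sample_counts <- function(fractions, mean_depth = 30) {
  tot <- matrix(rpois(length(fractions), mean_depth) + 1L,
                nrow(fractions), ncol(fractions))
  m <- matrix(rbinom(length(tot), as.vector(tot), as.vector(fractions)),
              nrow(fractions), ncol(fractions))
  list(meth = m, total = tot)
}

## A small GFF3 annotation written from explicit gene tuples:
## list(list(id, strand, start, end, exons = list(c(s, e), ...)), ...)
write_gff <- function(genes, chrom_len, chrom = "chr1",
                      path = tempfile(fileext = ".gff3")) {
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", chrom, chrom_len))
  for (g in genes) {
    lines <- c(lines,
      sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              chrom, g$start, g$end, g$strand, g$id),
      sprintf("%s\ttest\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              chrom, g$start, g$end, g$strand, g$id, g$id))
    exons <- g$exons %||% list(c(g$start, g$end))
    for (i in seq_along(exons)) {
      lines <- c(lines,
        sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s.t1",
                chrom, exons[[i]][1], exons[[i]][2], g$strand, g$id, i, g$id))
    }
    for (u in (g$utr5 %||% list())) {
      lines <- c(lines,
        sprintf("%s\ttest\tfive_prime_UTR\t%d\t%d\t.\t%s\t.\tID=%s.u5;Parent=%s.t1",
                chrom, u[1], u[2], g$strand, g$id, g$id))
    }
    for (u in (g$utr3 %||% list())) {
      lines <- c(lines,
        sprintf("%s\ttest\tthree_prime_UTR\t%d\t%d\t.\t%s\t.\tID=%s.u3;Parent=%s.t1",
                chrom, u[1], u[2], g$strand, g$id, g$id))
    }
  }
  writeLines(lines, path)
  path
}

## Population map for k populations of n individuals.
make_popmap <- function(k = 2L, n = 10L,
                        sites = sprintf("P%d", seq_len(k))) {
  data.frame(
    individual = unlist(lapply(sites, function(s) sprintf("%s_%02d", s, 1:n))),
    site = rep(sites, each = n),
    meta_population = rep(rep(c("pop1", "pop2"), length.out = k), each = n),
    stringsAsFactors = FALSE)
}
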