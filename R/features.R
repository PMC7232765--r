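## Genomic feature model from GFF3, tile classification, random-tile null
## sets, and feature-distribution comparison.

.readSeqlensFromGff <- function(path) {
  hdr <- grep("^##sequence-region", readLines(path), value = TRUE)
  if (!length(hdr)) return(NULL)
  parts <- strsplit(trimws(hdr), "\\s+")
  lens <- vapply(parts, function(p) as.numeric(p[4]), 0)
  names(lens) <- vapply(parts, function(p) p[2], "")
  lens
}

#' Build a feature model from GFF3
#'
#' Derives the promoter / 5'UTR / exon / intron / 3'UTR / downstream
#' annotation used for tile classification. Introns are the gene span minus
#' its exons; UTRs are taken from the GFF3 when present (exon ends otherwise
#' simply stay "exon"); promoter and downstream regions are strand-aware
#' `flank`-bp extensions clipped at chromosome bounds. Chromosome lengths
#' come from `##sequence-region` directives (or, failing that, the rightmost
#' feature end per chromosome).
#'
#' @param gff3 path to a GFF3 file with gene/mRNA/exon (UTRs optional).
#' @param flank promoter/downstream flank in bp (default 2000).
#' @return A [FeatureModel-class].
#' @export
buildFeatureModel <- function(gff3, flank = 2000L) {
  if (!file.exists(gff3))
    epiStop("epiDiverge_io_error", "GFF3 not found: %s", gff3)
  gr <- rtracklayer::import(gff3, format = "gff3")
  seqlens <- .readSeqlensFromGff(gff3)
  if (is.null(seqlens)) {
    seqlens <- vapply(split(end(gr), as.character(seqnames(gr))), max, 0)
  }
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  if (!length(genes))
    epiStop("epiDiverge_gff_error", "no gene features in %s", gff3)
  gene_ids <- genes$ID %||% as.character(seq_along(genes))
  mcols(genes) <- DataFrame(gene_id = gene_ids)

  ## map transcripts to genes; features parented by a transcript inherit its
  ## gene. Take the first mRNA per gene (no isoform resolution).
  tx <- gr[type %in% c("mRNA", "transcript")]
  tx_parent <- vapply(as.list(tx$Parent), function(p) p[1] %||% NA_character_, "")
  first_tx <- !duplicated(tx_parent)
  tx <- tx[first_tx]; tx_parent <- tx_parent[first_tx]
  tx2gene <- setNames(tx_parent, tx$ID)

  featureOf <- function(what) {
    sub <- gr[type == what]
    if (!length(sub)) {
      out <- GRanges()
      mcols(out)$gene_id <- character(0)
      return(out)
    }
    par <- vapply(as.list(sub$Parent), function(p) p[1] %||% NA_character_, "")
    gid <- ifelse(par %in% names(tx2gene), unname(tx2gene[par]), par)
    keep <- gid %in% gene_ids
    sub <- sub[keep]
    mcols(sub) <- DataFrame(gene_id = gid[keep])
    sub
  }
  exons <- featureOf("exon")
  utr5 <- featureOf("five_prime_UTR")
  utr3 <- featureOf("three_prime_UTR")

  ## exon containment check
  if (length(exons)) {
    idx <- match(mcols(exons)$gene_id, mcols(genes)$gene_id)
    bad <- start(exons) < start(genes)[idx] | end(exons) > end(genes)[idx] |
      as.character(seqnames(exons)) != as.character(seqnames(genes))[idx]
    if (any(bad))
      epiStop("epiDiverge_gff_error",
              "exon outside its gene span (gene %s)",
              mcols(exons)$gene_id[which(bad)[1L]])
  }

  ## introns: per gene, gene span minus exon cover
  intron_list <- lapply(seq_along(genes), function(i) {
    gid <- mcols(genes)$gene_id[i]
    ex <- exons[mcols(exons)$gene_id == gid]
    if (!length(ex)) return(GRanges())
    ir <- GenomicRanges::setdiff(granges(genes[i]), reduce(granges(ex)),
                                 ignore.strand = TRUE)
    ir
  })
  introns <- do.call(c, c(list(GRanges()), intron_list))
  gid_rep <- rep(mcols(genes)$gene_id, vapply(intron_list, length, 0L))
  mcols(introns) <- DataFrame(gene_id = gid_rep)

  lim <- seqlens[as.character(seqnames(genes))]
  plus <- as.character(strand(genes)) != "-"
  prom_start <- ifelse(plus, pmax(1, start(genes) - flank), end(genes) + 1)
  prom_end <- ifelse(plus, start(genes) - 1, pmin(lim, end(genes) + flank))
  down_start <- ifelse(plus, end(genes) + 1, pmax(1, start(genes) - flank))
  down_end <- ifelse(plus, pmin(lim, end(genes) + flank), start(genes) - 1)
  mkFlank <- function(s, e) {
    keep <- e >= s
    out <- GRanges(seqnames(genes)[keep], IRanges(s[keep], e[keep]),
                   strand = strand(genes)[keep])
    mcols(out) <- DataFrame(gene_id = mcols(genes)$gene_id[keep])
    out
  }
  feats <- GRangesList(
    promoter = mkFlank(prom_start, prom_end),
    five_prime_UTR = granges5(utr5),
    exon = granges5(exons),
    intron = introns,
    three_prime_UTR = granges5(utr3),
    downstream = mkFlank(down_start, down_end))
  new("FeatureModel", genes = genes, features = feats,
      seqlens = seqlens, flank = as.integer(flank))
}

## keep only the gene_id metadata column (GRangesList needs uniform mcols)
granges5 <- function(gr) {
  out <- granges(gr)
  mcols(out) <- DataFrame(gene_id = if (length(gr)) mcols(gr)$gene_id else character(0))
  out
}

#' @importFrom GenomicRanges granges
NULL

#' Classify tiles against a feature model
#'
#' Assigns each tile the category with the largest base-pair overlap; ties
#' break by precedence 5'UTR > 3'UTR > exon > intron > promoter >
#' downstream. Tiles overlapping no gene-linked category are `intergenic`
#' and annotated with the nearest gene by midpoint distance (NA when the
#' model has no genes). Overlaps ignore strand.
#'
#' @param tiles a `GRanges` of regions (or a [MethylTileSet-class]).
#' @param model a [FeatureModel-class].
#' @return data.frame with `tile`, `category`, `gene_id`.
#' @export
classifyRegions <- function(tiles, model) {
  stopifnot(is(model, "FeatureModel"))
  if (is(tiles, "MethylTileSet")) tiles <- rowRanges(tiles)
  n <- length(tiles)
  if (!n) return(data.frame(tile = character(), category = character(),
                            gene_id = character()))
  unknown <- !as.character(seqnames(tiles)) %in% names(model@seqlens)
  if (any(unknown))
    epiStop("epiDiverge_annot_error", "tile on unknown chromosome: %s",
            as.character(seqnames(tiles))[which(unknown)[1L]])
  ov <- matrix(0L, n, length(.FEATURE_PRECEDENCE),
               dimnames = list(NULL, .FEATURE_PRECEDENCE))
  best_gene <- matrix(NA_character_, n, length(.FEATURE_PRECEDENCE))
  for (j in seq_along(.FEATURE_PRECEDENCE)) {
    cat_nm <- .FEATURE_PRECEDENCE[j]
    fr <- model@features[[cat_nm]]
    if (!length(fr)) next
    hit <- findOverlaps(tiles, fr, ignore.strand = TRUE)
    if (!length(hit)) next
    w <- width(pintersect(tiles[S4Vectors::queryHits(hit)],
                          fr[S4Vectors::subjectHits(hit)], ignore.strand = TRUE))
    agg <- tapply(w, S4Vectors::queryHits(hit), sum)
    ov[as.integer(names(agg)), j] <- as.integer(agg)
    ## remember the gene contributing the widest single overlap
    ord <- order(S4Vectors::queryHits(hit), -w)
    firsts <- !duplicated(S4Vectors::queryHits(hit)[ord])
    qi <- S4Vectors::queryHits(hit)[ord][firsts]
    best_gene[qi, j] <- mcols(fr)$gene_id[S4Vectors::subjectHits(hit)[ord][firsts]]
  }
  ## precedence order is the column order, so max.col(ties = "first") breaks
  ## equal overlaps by precedence
  has_ov <- rowSums(ov) > 0L
  pick <- max.col(ov, ties.method = "first")
  category <- ifelse(has_ov, .FEATURE_PRECEDENCE[pick], "intergenic")
  gene_id <- ifelse(has_ov, best_gene[cbind(seq_len(n), pick)], NA_character_)

  if (any(!has_ov) && length(model@genes)) {
    ig <- which(!has_ov)
    tm <- (start(tiles)[ig] + end(tiles)[ig]) / 2
    gm_mid <- (start(model@genes) + end(model@genes)) / 2
    gchr <- as.character(seqnames(model@genes))
    tchr <- as.character(seqnames(tiles))[ig]
    gene_id[ig] <- vapply(seq_along(ig), function(i) {
      same <- gchr == tchr[i]
      if (!any(same)) return(NA_character_)
      j <- which(same)[which.min(abs(gm_mid[same] - tm[i]))]
      mcols(model@genes)$gene_id[j]
    }, "")
  }
  tile_names <- names(tiles) %||%
    paste0(seqnames(tiles), ":", start(tiles) - 1L)
  data.frame(tile = tile_names,
             category = factor(category, levels = .FEATURE_CATEGORIES),
             gene_id = gene_id, row.names = NULL, stringsAsFactors = FALSE)
}

#' Feature distribution of a set of classified tiles
#'
#' @param categories factor/character of category labels (from
#'   [classifyRegions()]'s `category` column).
#' @return named numeric vector of fractions over the seven categories
#'   (sums to 1), with attribute `n_tiles`.
#' @export
featureDistribution <- function(categories) {
  categories <- factor(as.character(categories), levels = .FEATURE_CATEGORIES)
  if (any(is.na(categories)))
    epiStop("epiDiverge_annot_error", "unknown feature category")
  n <- length(categories)
  if (!n) epiStop("epiDiverge_annot_error", "no tiles to summarize")
  out <- as.numeric(table(categories)) / n
  names(out) <- .FEATURE_CATEGORIES
  attr(out, "n_tiles") <- n
  out
}

#' Generate random genome-wide tile sets
#'
#' Draws `n_sets` independent sets of `n_per_set` tiles of width `tile`,
#' uniformly over positions (chromosomes weighted by their number of valid
#' start positions). Tiles may overlap each other and genes. An optional
#' `mask` (GRanges, e.g. assembly gaps) excludes any tile intersecting it by
#' redrawing.
#'
#' @param model a [FeatureModel-class] (supplies chromosome lengths).
#' @param n_per_set tiles per set (default 39053).
#' @param n_sets number of sets (default 6).
#' @param seed integer seed.
#' @param tile tile width (default 100).
#' @param mask optional `GRanges` to exclude.
#' @return list of `GRanges`, one per set.
#' @export
generateRandomTiles <- function(model, n_per_set = 39053L, n_sets = 6L,
                                seed = 1L, tile = 100L, mask = NULL) {
  stopifnot(is(model, "FeatureModel"))
  if (n_per_set < 1L)
    epiStop("epiDiverge_annot_error", "n_per_set must be >= 1")
  lens <- model@seqlens
  valid <- floor(lens) - tile + 1
  if (all(valid < 1))
    epiStop("epiDiverge_annot_error",
            "no chromosome can hold a %d-bp tile", tile)
  valid[valid < 0] <- 0
  set.seed(deriveSeed(seed, 5L))
  lapply(seq_len(n_sets), function(s) {
    draw <- function(n) {
      chr <- sample(names(lens), n, replace = TRUE, prob = valid)
      st <- floor(runif(n, 0, valid[chr])) + 1   # 1-based start
      GRanges(chr, IRanges(as.integer(st), width = tile))
    }
    gr <- draw(n_per_set)
    if (!is.null(mask)) {
      for (it in 1:50) {
        bad <- overlapsAny(gr, mask, ignore.strand = TRUE)
        if (!any(bad)) break
        gr[bad] <- draw(sum(bad))
      }
    }
    gr
  })
}

#' @importFrom GenomicRanges overlapsAny
NULL

#' Exact base-pair category fractions of a feature model
#'
#' Assigns every base of the genome to one category using the classification
#' precedence, and returns the genome-wide fractions. This is the exact
#' counterpart that random-tile feature distributions estimate.
#'
#' @param model a [FeatureModel-class].
#' @return named numeric vector over the seven categories (sums to 1).
#' @export
featureBasePairFractions <- function(model) {
  stopifnot(is(model, "FeatureModel"))
  total <- sum(model@seqlens)
  taken <- GRanges()
  out <- numeric(length(.FEATURE_PRECEDENCE))
  names(out) <- .FEATURE_PRECEDENCE
  for (nm in .FEATURE_PRECEDENCE) {
    fr <- reduce(granges(model@features[[nm]]), ignore.strand = TRUE)
    uniq <- GenomicRanges::setdiff(fr, taken, ignore.strand = TRUE)
    out[nm] <- sum(width(uniq))
    taken <- reduce(c(taken, uniq), ignore.strand = TRUE)
  }
  out <- c(out, intergenic = total - sum(out))
  (out / total)[.FEATURE_CATEGORIES]
}

#' Compare two feature distributions with a Kolmogorov--Smirnov test
#'
#' Treats each fraction vector as a distribution of tiles over the fixed
#' category order and compares the two with the two-sample KS statistic,
#' `D = max |cumsum(observed) - cumsum(reference)|`. The p-value is obtained
#' by expanding each distribution back into its tile-count sample (category
#' indices repeated `fraction * n` times) and applying `stats::ks.test`;
#' `n1`/`n2` default to the `n_tiles` attribute that [featureDistribution()]
#' attaches. Because category distributions are heavily tied, the p-value is
#' the test's tie-approximate one; the per-set fractions should also be
#' inspected directly.
#'
#' @param observed,reference numeric fraction vectors in the same category
#'   order (e.g. from [featureDistribution()]).
#' @param n1,n2 tile counts behind each distribution (defaults: `n_tiles`
#'   attribute, else the vector length).
#' @return list with `D` (KS statistic) and `p_value`.
#' @export
compareFeatureDistributions <- function(observed, reference,
                                        n1 = NULL, n2 = NULL) {
  if (length(observed) != length(reference))
    epiStop("epiDiverge_annot_error",
            "distributions differ in length (%d vs %d)",
            length(observed), length(reference))
  n1 <- as.integer(n1 %||% attr(observed, "n_tiles") %||% length(observed))
  n2 <- as.integer(n2 %||% attr(reference, "n_tiles") %||% length(reference))
  p <- as.numeric(observed) / sum(observed)
  q <- as.numeric(reference) / sum(reference)
  D <- max(abs(cumsum(p) - cumsum(q)))
  x <- rep(seq_along(p), round(p * n1))
  y <- rep(seq_along(q), round(q * n2))
  pv <- if (D == 0) 1 else suppressWarnings(ks.test(x, y))$p.value
  list(D = D, p_value = pv)
}
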