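## Internal helpers shared across modules.

## Condition helper: errors carry a package-specific class so callers (and the
## pipeline driver) can catch them by name.
epiStop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "epiDiverge_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Resolve a grouping argument: either a factor/character aligned with the
## columns of a MethylTileSet, or the name of a colData column.
resolveGrouping <- function(x, groups) {
  if (is.character(groups) && length(groups) == 1L &&
      groups %in% colnames(colData(x))) {
    groups <- colData(x)[[groups]]
  }
  if (length(groups) != ncol(x))
    epiStop("epiDiverge_grouping_error",
            "grouping has %d entries for %d samples", length(groups), ncol(x))
  factor(as.character(groups))
}

## 0/1 indicator matrix (samples x groups) for pooled-count arithmetic.
groupIndicator <- function(groups) {
  groups <- factor(groups)
  ind <- vapply(levels(groups), function(l) as.numeric(groups == l),
                numeric(length(groups)))
  ind <- matrix(ind, nrow = length(groups),
                dimnames = list(NULL, levels(groups)))
  ind
}

## Row-wise sample variances (denominator n-1) over the columns selected by a
## group indicator; NA entries in `m` are excluded per cell. Two-pass
## computation (explicit deviations from the group mean) for numerical
## stability. Returns a matrix tiles x groups with NA where fewer than 2
## defined values.
rowVarByGroup <- function(m, ind) {
  ok <- !is.na(m)
  m0 <- m
  m0[!ok] <- 0
  n  <- ok %*% ind                      # regions x groups
  mu <- (m0 %*% ind) / n                # group means
  ## expand group means back to cells and take explicit deviations
  col_group <- max.col(ind, ties.method = "first")   # sample -> group index
  dev <- m0 - mu[, col_group, drop = FALSE]
  dev[!ok] <- 0
  ss <- (dev * dev) %*% ind
  v <- ss / (n - 1)
  v[n < 2] <- NA_real_
  v
}

## Deterministic per-purpose seeds derived from one master seed, kept within
## 32-bit integer range.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
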