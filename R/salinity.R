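## Salinity stress-index profiling: five bins that track oyster salinity
## tolerance (>20 psu no negative effects; 15-20 reduced reproduction; 6-15
## reduced spat recruitment; 3.5-6 reduced growth; 0-3.5 survival limited to
## ~5 months), plus the 10-day pre-collection window mean.

.SALINITY_BREAKS <- c(0, 3.5, 6, 15, 20, Inf)
.SALINITY_BINS <- c("psu_0_3.5", "psu_3.5_6", "psu_6_15", "psu_15_20",
                    "psu_gt_20")

#' Read a daily salinity CSV
#'
#' Expects columns `site`, `date` (ISO-8601), `psu` and optionally
#' `temperature`. Multiple measurements on the same site-day are averaged to
#' one daily value.
#'
#' @param path CSV path.
#' @return data.frame with one row per site-day.
#' @export
readSalinityCsv <- function(path) {
  if (!file.exists(path))
    epiStop("epiDiverge_io_error", "salinity CSV not found: %s", path)
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  if (!all(c("site", "date", "psu") %in% colnames(df)))
    epiStop("epiDiverge_io_error", "salinity CSV needs site, date, psu columns")
  df$date <- as.Date(df$date)
  key <- paste(df$site, df$date)
  if (anyDuplicated(key)) {
    agg <- stats::aggregate(df[intersect(c("psu", "temperature"), colnames(df))],
                     by = list(site = df$site, date = df$date), FUN = mean)
    df <- agg[order(agg$site, agg$date), , drop = FALSE]
  }
  df
}

#' Bin daily salinities into the five stress regimes
#'
#' Each day falls in exactly one bin; boundaries are upper-exclusive at
#' 3.5/6/15 psu and the top bin is lower-inclusive at 20 psu, so a day at
#' exactly 20 psu counts as ">20" and "time above 15 psu" is the sum of the
#' top two bins. Missing values are skipped and counted.
#'
#' @param psu numeric vector of daily salinities (psu, >= 0).
#' @param site optional site label carried into the output.
#' @return list with `site`, `fractions` (named, sums to 1, ordered low to
#'   high), `n_days` (non-missing), `n_missing`, `mean_psu`.
#' @examples
#' binSalinityFractions(c(2, 2, 3, 4, 7, 16, 21, 25, 10, 5))$fractions
#' @export
binSalinityFractions <- function(psu, site = NA_character_) {
  n_missing <- sum(is.na(psu))
  v <- psu[!is.na(psu)]
  if (!length(v))
    epiStop("epiDiverge_salinity_error", "no non-missing days to bin")
  if (any(v < 0))
    epiStop("epiDiverge_salinity_error", "negative salinity value: %g",
            min(v))
  bins <- cut(v, breaks = .SALINITY_BREAKS, right = FALSE,
              include.lowest = TRUE, labels = .SALINITY_BINS)
  fr <- as.numeric(table(bins)) / length(v)
  names(fr) <- .SALINITY_BINS
  list(site = site, fractions = fr, n_days = length(v),
       n_missing = n_missing, mean_psu = mean(v))
}

#' Mean salinity over the pre-collection window
#'
#' Arithmetic mean of the available daily values in the `window` days
#' strictly before `collection_date` (i.e. dates in
#' `[collection_date - window, collection_date - 1]`). Missing days are
#' skipped and counted; a window with no observations is an error.
#'
#' @param df data.frame with `date` and a value column.
#' @param collection_date Date or ISO-8601 string.
#' @param window window length in days (default 10).
#' @param value name of the value column (default `"psu"`).
#' @return list with `mean`, `n_days`, `n_missing`.
#' @export
windowMean <- function(df, collection_date, window = 10L, value = "psu") {
  collection_date <- as.Date(collection_date)
  dates <- as.Date(df$date)
  sel <- dates >= collection_date - window & dates < collection_date
  v <- df[[value]][sel]
  v <- v[!is.na(v)]
  if (!length(v))
    epiStop("epiDiverge_salinity_error",
            "no observations in the %d days before %s", window,
            format(collection_date))
  list(mean = mean(v), n_days = length(v),
       n_missing = as.integer(window) - length(v))
}

#' Stress profiles for every site of a salinity table
#'
#' @param df long data.frame from [readSalinityCsv()].
#' @param collection_dates optional named vector (site -> ISO date) adding a
#'   pre-collection `window`-day mean per site.
#' @param window pre-collection window in days (default 10).
#' @return data.frame, one row per site: bin fractions, day counts, mean
#'   salinity, and (when requested) the window mean.
#' @export
salinityProfiles <- function(df, collection_dates = NULL, window = 10L) {
  sites <- unique(df$site)
  rows <- lapply(sites, function(s) {
    sub <- df[df$site == s, , drop = FALSE]
    pr <- binSalinityFractions(sub$psu, site = s)
    row <- data.frame(site = s, t(pr$fractions), n_days = pr$n_days,
                      n_missing = pr$n_missing, mean_psu = pr$mean_psu,
                      check.names = FALSE, stringsAsFactors = FALSE)
    if (!is.null(collection_dates)) {
      if (s %in% names(collection_dates)) {
        wm <- windowMean(sub, collection_dates[[s]], window = window)
        row$window_mean_psu <- wm$mean
        row$window_n_missing <- wm$n_missing
      } else {
        row$window_mean_psu <- NA_real_
        row$window_n_missing <- NA_integer_
      }
    }
    row
  })
  do.call(rbind, rows)
}
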