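# Longitudinal analysis of a year-indexed metric series: least-squares
# changepoint segmentation into periods, per-period summaries, and pairwise
# t-tests between periods.

#' Build a metric series from a metrics table
#'
#' @param table data.frame with columns `year` and the chosen metric
#'   (e.g. the output of [metricsTable()]).
#' @param metric column name to extract (default `"percent_v"`).
#' @param idColumn column holding sample ids (default `"sample_id"`).
#' @return data.frame with columns `year`, `value`, `sampleId`, sorted by
#'   year then id; multiple samples per year are allowed.
#' @export
metricSeries <- function(table, metric = "percent_v",
                         idColumn = "sample_id") {
  if (!(metric %in% names(table)))
    srStop("parseError", "no column '%s' in metrics table", metric)
  ids <- if (idColumn %in% names(table)) table[[idColumn]]
         else as.character(seq_len(nrow(table)))
  out <- data.frame(year = as.integer(table$year),
                    value = as.numeric(table[[metric]]),
                    sampleId = ids, stringsAsFactors = FALSE)
  out <- out[!is.na(out$value) & !is.na(out$year), , drop = FALSE]
  out <- out[order(out$year, out$sampleId), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.asSeries <- function(series) {
  stopifnot(all(c("year", "value") %in% names(series)))
  series[order(series$year), , drop = FALSE]
}

# RSS of a piecewise-constant fit with the given break years.
.partitionRss <- function(year, value, breaks) {
  seg <- findInterval(year, breaks) # 0..k
  sum(tapply(value, seg, function(v) sum((v - mean(v))^2)))
}

#' Least-squares changepoint segmentation of a year series
#'
#' Exhaustively searches placements of `k` break years (a break year is the
#' first year of the new period) minimizing the total within-period sum of
#' squared deviations from period means. Series here are small (tens of
#' observations), so exhaustive search is exact and cheap. Ties are broken
#' in favour of the earliest break years.
#'
#' @param series data.frame with columns `year`, `value` (see
#'   [metricSeries()]).
#' @param k number of breakpoints (default 2, giving three periods).
#' @return a [PeriodPartition-class].
#' @examples
#' s <- data.frame(year = 2006:2010, value = c(45, 45, 45, 50, 50))
#' findChangepoints(s, k = 1)  # break at 2009
#' @export
findChangepoints <- function(series, k = 2L) {
  series <- .asSeries(series)
  k <- as.integer(k)
  if (k < 1L) srStop("badConfig", "k must be >= 1")
  years <- sort(unique(series$year))
  if (length(years) < k + 1L || nrow(series) < k + 2L)
    srStop("badConfig",
           "series too short for %d breakpoint(s): %d distinct years, %d observations",
           k, length(years), nrow(series))
  candidates <- years[-1L]
  combos <- utils::combn(candidates, k)
  rss0 <- sum((series$value - mean(series$value))^2)
  best <- NULL
  bestRss <- Inf
  for (j in seq_len(ncol(combos))) {
    r <- .partitionRss(series$year, series$value, combos[, j])
    if (r < bestRss - 1e-12) {       # strict improvement: earliest combo wins ties
      bestRss <- r
      best <- combos[, j]
    }
  }
  periods <- data.frame(startYear = c(min(years), best),
                        endYear = c(best - 1L, max(years)))
  new("PeriodPartition", breakYears = as.numeric(best), periods = periods,
      rss = bestRss, improvement = rss0 - bestRss)
}

# Period index (1-based) of each observation under a partition.
.periodIndex <- function(year, partition) {
  findInterval(year, partition@breakYears) + 1L
}

#' Per-period summaries of a metric series
#'
#' @param series data.frame with columns `year`, `value`.
#' @param partition a [PeriodPartition-class].
#' @return data.frame with one row per period: `period`, `startYear`,
#'   `endYear`, `n`, `mean`, `sd` (NA for single-observation periods),
#'   `min`, `max`.
#' @export
summarizePeriods <- function(series, partition) {
  series <- .asSeries(series)
  idx <- .periodIndex(series$year, partition)
  nPeriods <- length(partition@breakYears) + 1L
  empty <- setdiff(seq_len(nPeriods), unique(idx))
  if (length(empty))
    srStop("emptyPeriod", "period %d contains no observations", empty[1L])
  rows <- lapply(seq_len(nPeriods), function(p) {
    v <- series$value[idx == p]
    data.frame(period = p,
               startYear = partition@periods$startYear[p],
               endYear = partition@periods$endYear[p],
               n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               min = min(v), max = max(v))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise t-tests between periods of a metric series
#'
#' Runs a two-sample t-test for each adjacent pair of periods (all pairs
#' with `allPairs = TRUE`). The default is Welch's unequal-variance test;
#' `test = "pooled"` gives the classical pooled-SD test. p-values are
#' reported per comparison without multiplicity correction.
#'
#' @param series data.frame with columns `year`, `value`.
#' @param partition a [PeriodPartition-class].
#' @param test `"welch"` (default) or `"pooled"`.
#' @param allPairs compare all period pairs instead of adjacent only.
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @return a [PeriodComparison-class].
#' @export
comparePeriods <- function(series, partition, test = c("welch", "pooled"),
                           allPairs = FALSE, alpha = 0.05) {
  test <- match.arg(test)
  series <- .asSeries(series)
  summaries <- summarizePeriods(series, partition)
  idx <- .periodIndex(series$year, partition)
  nPeriods <- length(partition@breakYears) + 1L
  pairs <- if (allPairs) utils::combn(nPeriods, 2L)
           else rbind(seq_len(nPeriods - 1L), seq.int(2L, nPeriods))
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    x <- series$value[idx == a]; y <- series$value[idx == b]
    if (length(x) < 2L || length(y) < 2L)
      srStop("insufficientN",
             "period %d vs %d: need n >= 2 in both periods (have %d, %d)",
             a, b, length(x), length(y))
    tt <- stats::t.test(x, y, var.equal = (test == "pooled"))
    data.frame(periodA = a, periodB = b,
               t = unname(tt$statistic), df = unname(tt$parameter),
               pValue = tt$p.value, significant = tt$p.value < alpha)
  })
  tests <- do.call(rbind, rows)
  rownames(tests) <- NULL
  new("PeriodComparison", summaries = summaries, tests = tests,
      test = test, alpha = alpha)
}
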