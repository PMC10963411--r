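#' Accessors for SpeechRhythm objects
#'
#' Small accessor generics in place of direct slot access.
#'
#' @param x an object of the appropriate class.
#' @return `intervals()`: the interval data.frame; `sampleId()`: the sample
#'   identifier; `recordingYear()`: the integer year; `phonationTime()`:
#'   summed V+C duration (s); `sampleSpan()`: total recording span (s);
#'   `curvePoints()`: the stabilization curve data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intervals", function(x) standardGeneric("intervals"))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("recordingYear", function(x) standardGeneric("recordingYear"))

#' @rdname accessors
#' @export
setGeneric("phonationTime", function(x) standardGeneric("phonationTime"))

#' @rdname accessors
#' @export
setGeneric("sampleSpan", function(x) standardGeneric("sampleSpan"))

#' @rdname accessors
#' @export
setGeneric("curvePoints", function(x) standardGeneric("curvePoints"))

#' @rdname accessors
#' @export
setMethod("intervals", "SpeechSample", function(x) x@intervals)

#' @rdname accessors
#' @export
setMethod("sampleId", "SpeechSample", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("recordingYear", "SpeechSample", function(x) x@year)

#' @rdname accessors
#' @export
setMethod("phonationTime", "SpeechSample", function(x) {
  iv <- x@intervals
  keep <- iv$label %in% c("V", "C")
  sum(iv$end[keep] - iv$start[keep])
})

#' @rdname accessors
#' @export
setMethod("sampleSpan", "SpeechSample", function(x) {
  iv <- x@intervals
  if (nrow(iv) == 0L) return(0)
  max(iv$end) - min(iv$start)
})

#' @rdname accessors
#' @export
setMethod("curvePoints", "StabilizationCurve", function(x) x@points)

setMethod("show", "SpeechSample", function(object) {
  iv <- object@intervals
  counts <- table(factor(iv$label, levels = .VALID_LABELS))
  cat(sprintf("SpeechSample '%s'%s: %d intervals, span %.2f s, phonation %.2f s\n",
              object@sampleId,
              if (is.na(object@year)) "" else sprintf(" (%d)", object@year),
              nrow(iv), sampleSpan(object), phonationTime(object)))
  cat(sprintf("  V: %d  C: %d  D: %d  X: %d\n",
              counts[["V"]], counts[["C"]], counts[["D"]], counts[["X"]]))
})

setMethod("show", "RhythmMetrics", function(object) {
  cat(sprintf("RhythmMetrics '%s'%s\n", object@sampleId,
              if (is.na(object@year)) "" else sprintf(" (%d)", object@year)))
  cat(sprintf("  %%V = %.2f   VtoV = %.1f ms   AR = %.2f syll/s\n",
              object@percentV, object@vtovMs, object@arSyllPerS))
  cat(sprintf("  phonation %.2f s over %d V / %d C intervals (%d D, %d X excluded); %d onset intervals\n",
              object@phonationS, object@nV, object@nC, object@nD, object@nX,
              object@nVtoVIntervals))
  if (isTRUE(object@belowMinDuration))
    cat("  [flag] sample shorter than the minimum reliable duration\n")
})

setMethod("show", "StabilizationCurve", function(object) {
  p <- object@points
  cat(sprintf("StabilizationCurve '%s': %d windows of step %g s (%g-%g s)\n",
              object@sampleId, nrow(p), object@stepS,
              if (nrow(p)) min(p$windowS) else NA,
              if (nrow(p)) max(p$windowS) else NA))
})

setMethod("show", "StabilizationSummary", function(object) {
  cat(sprintf("StabilizationSummary (%s SD):\n", object@sdType))
  print(object@bands, row.names = FALSE)
  cat(sprintf("  recommended minimum duration: %s s\n",
              format(object@recommendedMinS)))
})

setMethod("show", "PeriodPartition", function(object) {
  cat(sprintf("PeriodPartition: %d period(s), breaks at %s\n",
              nrow(object@periods),
              if (length(object@breakYears))
                paste(object@breakYears, collapse = ", ") else "none"))
  print(object@periods, row.names = FALSE)
  cat(sprintf("  RSS %.4g (improvement over no split: %.4g)\n",
              object@rss, object@improvement))
})

setMethod("show", "PeriodComparison", function(object) {
  cat(sprintf("PeriodComparison (%s t-test, alpha = %g)\n",
              object@test, object@alpha))
  print(object@summaries, row.names = FALSE)
  print(object@tests, row.names = FALSE)
})

#' Flatten a RhythmMetrics object into a one-row data.frame
#'
#' Columns follow the package's metrics-table convention:
#' `sample_id, year, percent_v, vtov_ms, ar, n_v, n_c, n_d, n_x,
#' phonation_s, n_vtov_intervals, below_min_duration`.
#'
#' @param x a [RhythmMetrics-class] object.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return one-row data.frame.
#' @export
as.data.frame.RhythmMetrics <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(sample_id = x@sampleId, year = x@year,
             percent_v = x@percentV, vtov_ms = x@vtovMs,
             ar = x@arSyllPerS, n_v = x@nV, n_c = x@nC,
             n_d = x@nD, n_x = x@nX, phonation_s = x@phonationS,
             n_vtov_intervals = x@nVtoVIntervals,
             below_min_duration = x@belowMinDuration,
             stringsAsFactors = FALSE)
}
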