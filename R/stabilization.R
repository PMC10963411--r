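# Minimum-duration (stabilization) analysis: rhythm metrics on cumulative
# windows growing in fixed steps, with band-wise SD summaries. Window length
# is recording time (pauses and disfluencies included); the metrics computed
# on each window still exclude D and X.

# Truncate a sample at elapsed time L from its start. "split" keeps the left
# part of the straddling interval (window is exactly L seconds); "drop"
# discards the straddler.
truncateSample <- function(sample, lengthS,
                           partialInterval = c("split", "drop")) {
  partialInterval <- match.arg(partialInterval)
  iv <- intervals(sample)
  if (nrow(iv) == 0L) return(sample)
  t0 <- min(iv$start)
  cut <- t0 + lengthS
  keep <- iv$start < cut - .TIME_TOL
  iv <- iv[keep, , drop = FALSE]
  straddle <- iv$end > cut + .TIME_TOL
  if (partialInterval == "split") {
    iv$end[straddle] <- cut
  } else if (any(straddle)) {
    iv <- iv[!straddle, , drop = FALSE]
  }
  out <- sample
  out@intervals <- iv
  rownames(out@intervals) <- NULL
  out
}

#' Stabilization curve: metrics over cumulative windows
#'
#' Computes %V and VtoV on prefixes of the sample truncated at elapsed
#' lengths `stepS`, `2*stepS`, ... up to the sample span. The interval
#' straddling a window boundary is split and its left part kept (so every
#' window is exactly its nominal length) unless `partialInterval = "drop"`.
#' A metric undefined on a short prefix is recorded as NA.
#'
#' @param sample a [SpeechSample-class] spanning at least `stepS` seconds.
#' @param stepS window increment in seconds (default 10).
#' @param partialInterval `"split"` (default) or `"drop"`.
#' @return a [StabilizationCurve-class].
#' @export
stabilizationCurve <- function(sample, stepS = 10,
                               partialInterval = c("split", "drop")) {
  partialInterval <- match.arg(partialInterval)
  stopifnot(is(sample, "SpeechSample"), stepS > 0)
  span <- sampleSpan(sample)
  nWin <- floor(span / stepS + .TIME_TOL)
  if (nWin < 1L)
    srStop("emptyCurve",
           "sample '%s' spans %.2f s, shorter than one %g s step",
           sampleId(sample), span, stepS)
  lens <- stepS * seq_len(nWin)
  pv <- vt <- rep(NA_real_, nWin)
  for (i in seq_len(nWin)) {
    tr <- truncateSample(sample, lens[i], partialInterval)
    pv[i] <- tryCatch(percentV(tr),
                      SpeechRhythm_undefinedMetric = function(e) NA_real_)
    vt[i] <- tryCatch(vtov(tr)$vtovMs,
                      SpeechRhythm_undefinedMetric = function(e) NA_real_)
  }
  new("StabilizationCurve", sampleId = sampleId(sample), stepS = stepS,
      points = data.frame(windowS = lens, percentV = pv, vtovMs = vt))
}

.DEFAULT_BANDS <- list(c(10, 40), c(50, 80), c(90, Inf))

#' Band-wise variability summary of a stabilization curve
#'
#' Computes the SD of each metric over the curve points whose window length
#' falls inside each band (inclusive bounds). The recommended minimum
#' duration is the lower edge of the first band whose %V SD falls below
#' `sdThresholdPercentV`. Curve points falling between bands (e.g. 40-50 s
#' with the default bands) belong to no band.
#'
#' @param curve a [StabilizationCurve-class].
#' @param bands list of `c(lo, hi)` windows in seconds; defaults to
#'   10-40 s, 50-80 s and >= 90 s.
#' @param sdThresholdPercentV stability threshold on the %V SD in
#'   percentage points (default 0.5).
#' @param sdType `"sample"` (n-1 denominator, default) or `"population"`.
#' @return a [StabilizationSummary-class]; a band containing fewer than two
#'   points has NA SDs.
#' @export
bandSummary <- function(curve, bands = .DEFAULT_BANDS,
                        sdThresholdPercentV = 0.5,
                        sdType = c("sample", "population")) {
  sdType <- match.arg(sdType)
  stopifnot(is(curve, "StabilizationCurve"))
  p <- curvePoints(curve)
  if (nrow(p) == 0L)
    srStop("emptyCurve", "cannot summarize an empty curve")
  lo <- vapply(bands, `[`, 0, 1L)
  hi <- vapply(bands, `[`, 0, 2L)
  if (is.unsorted(lo) || any(lo[-1L] <= hi[-length(hi)]))
    srStop("badBands", "bands must be ordered and non-overlapping")
  sdPv <- sdVt <- rep(NA_real_, length(bands))
  nPts <- integer(length(bands))
  for (i in seq_along(bands)) {
    inB <- p$windowS >= lo[i] - .TIME_TOL & p$windowS <= hi[i] + .TIME_TOL
    nPts[i] <- sum(inB)
    if (nPts[i] > 0L) {
      sdPv[i] <- sdBy(p$percentV[inB], sdType)
      sdVt[i] <- sdBy(p$vtovMs[inB], sdType)
    }
  }
  ok <- which(!is.na(sdPv) & sdPv < sdThresholdPercentV)
  recommended <- if (length(ok)) lo[ok[1L]] else NA_real_
  new("StabilizationSummary",
      bands = data.frame(loS = lo, hiS = hi, sdPercentV = sdPv,
                         sdVtovMs = sdVt, nPoints = nPts),
      recommendedMinS = recommended, sdType = sdType)
}

#' Mean band SDs across a corpus of samples
#'
#' Computes a per-sample [bandSummary()] and averages the band SDs
#' arithmetically across samples (samples where a band is empty are
#' omitted from that band's mean).
#'
#' @param samples list of [SpeechSample-class] objects (or of
#'   [StabilizationCurve-class] objects, in which case `stepS` is ignored).
#' @param stepS window increment passed to [stabilizationCurve()].
#' @inheritParams bandSummary
#' @return a [StabilizationSummary-class] holding the mean band SDs; its
#'   `nPoints` column counts contributing samples per band.
#' @export
corpusBandSummary <- function(samples, stepS = 10, bands = .DEFAULT_BANDS,
                              sdThresholdPercentV = 0.5,
                              sdType = c("sample", "population")) {
  sdType <- match.arg(sdType)
  if (length(samples) < 1L)
    srStop("emptyCurve", "need at least one sample")
  per <- lapply(samples, function(s) {
    cv <- if (is(s, "StabilizationCurve")) s else stabilizationCurve(s, stepS)
    bandSummary(cv, bands, sdThresholdPercentV, sdType)@bands
  })
  lo <- per[[1L]]$loS; hi <- per[[1L]]$hiS
  sdPvMat <- vapply(per, function(b) b$sdPercentV, numeric(length(lo)))
  sdVtMat <- vapply(per, function(b) b$sdVtovMs, numeric(length(lo)))
  sdPvMat <- matrix(sdPvMat, nrow = length(lo))
  sdVtMat <- matrix(sdVtMat, nrow = length(lo))
  meanPv <- rowMeans(sdPvMat, na.rm = TRUE)
  meanPv[is.nan(meanPv)] <- NA_real_
  meanVt <- rowMeans(sdVtMat, na.rm = TRUE)
  meanVt[is.nan(meanVt)] <- NA_real_
  nContrib <- rowSums(!is.na(sdPvMat))
  ok <- which(!is.na(meanPv) & meanPv < sdThresholdPercentV)
  recommended <- if (length(ok)) lo[ok[1L]] else NA_real_
  new("StabilizationSummary",
      bands = data.frame(loS = lo, hiS = hi, sdPercentV = meanPv,
                         sdVtovMs = meanVt, nPoints = as.integer(nContrib)),
      recommendedMinS = recommended, sdType = sdType)
}
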