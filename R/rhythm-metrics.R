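# Rhythm indexes: %V, VtoV and articulation rate.
#
# %V is the percentage of vocalic duration over phonation time (V + C only).
# Disfluencies (D) and silent pauses (X) are annotated but contribute to
# neither numerator nor denominator. VtoV is the mean interval between two
# consecutive vowel onsets; articulation rate is its reciprocal (AR = 1/VtoV).

#' Percentage of vocalic duration over phonation time (%V)
#'
#' Computes 100 * sum(V durations) / (sum(V) + sum(C)). Disfluency (D) and
#' pause (X) intervals are excluded from both numerator and denominator:
#' the denominator is phonation time, not total recording time.
#'
#' @param sample a [SpeechSample-class].
#' @return %V on the 0-100 scale.
#' @examples
#' s <- sampleFromDurations(c(0.12, 0.08, 0.1, 0.5, 0.06, 0.04),
#'                          c("V", "C", "V", "X", "C", "V"))
#' percentV(s)  # 65: 0.26 s vocalic out of 0.40 s phonation
#' @export
percentV <- function(sample) {
  stopifnot(is(sample, "SpeechSample"))
  iv <- intervals(sample)
  d <- iv$end - iv$start
  v <- sum(d[iv$label == "V"])
  c_ <- sum(d[iv$label == "C"])
  if (v + c_ <= 0)
    srStop("undefinedMetric",
           "%%V undefined: sample '%s' has zero phonation time",
           sampleId(sample))
  100 * v / (v + c_)
}

#' Mean vowel-onset-to-vowel-onset interval (VtoV)
#'
#' Vowel onsets are the start times of V intervals. Onset-to-onset
#' differences are averaged; under the default `"break"` policy a D or X
#' interval breaks the onset chain, so differences spanning a pause or
#' disfluency are discarded rather than inflated by the excluded material.
#' The `"concatenate"` policy instead deletes D/X intervals and closes the
#' gaps before measuring (provided for sensitivity analysis).
#'
#' @param sample a [SpeechSample-class].
#' @param chainPolicy `"break"` (default) or `"concatenate"`.
#' @return list with `vtovMs` (mean onset interval, ms) and `n`
#'   (number of onset-to-onset differences used).
#' @examples
#' s <- sampleFromDurations(c(0.1, 0.1, 0.1, 0.1, 0.1),
#'                          c("V", "C", "V", "C", "V"))
#' vtov(s)  # 200 ms from 2 onset intervals
#' @export
vtov <- function(sample, chainPolicy = c("break", "concatenate")) {
  stopifnot(is(sample, "SpeechSample"))
  chainPolicy <- match.arg(chainPolicy)
  iv <- intervals(sample)
  if (chainPolicy == "concatenate") {
    keep <- iv$label %in% c("V", "C")
    dur <- (iv$end - iv$start)[keep]
    lab <- iv$label[keep]
    if (!length(dur))
      srStop("undefinedMetric", "VtoV undefined: no V or C intervals")
    starts <- cumsum(c(0, dur[-length(dur)]))
    onsets <- starts[lab == "V"]
    diffs <- diff(onsets)
  } else {
    # chain id increments at every excluded (D/X) interval; onsets within
    # one chain are uninterrupted by excluded material
    chain <- cumsum(iv$label %in% c("D", "X"))
    isV <- iv$label == "V"
    onsets <- iv$start[isV]
    vchain <- chain[isV]
    diffs <- diff(onsets)[diff(vchain) == 0]
  }
  if (length(diffs) < 1L)
    srStop("undefinedMetric",
           "VtoV undefined: fewer than 2 chained vowel onsets in sample '%s'",
           sampleId(sample))
  list(vtovMs = mean(diffs) * 1000, n = length(diffs))
}

#' Convert VtoV (ms) to articulation rate (syllables/s)
#'
#' AR = 1000 / VtoV. The display convention truncates (floors) to one
#' decimal rather than rounding; full precision is available with
#' `decimalsMode = "none"`.
#'
#' @param vtovMs mean onset interval in milliseconds (> 0); vectorized.
#' @param decimalsMode `"truncate"` (default, floor to one decimal),
#'   `"round"`, or `"none"`.
#' @return articulation rate in syllables per second.
#' @examples
#' vtovToAR(c(196, 210, 224))  # 5.1, 4.7, 4.4
#' @export
vtovToAR <- function(vtovMs, decimalsMode = c("truncate", "round", "none")) {
  decimalsMode <- match.arg(decimalsMode)
  if (any(!is.finite(vtovMs)) || any(vtovMs <= 0))
    srStop("undefinedMetric", "VtoV must be positive and finite")
  ar <- 1000 / vtovMs
  switch(decimalsMode,
         truncate = truncDecimals(ar, 1L),
         round = round(ar, 1L),
         none = ar)
}

#' Compute all rhythm metrics for a sample
#'
#' Bundles %V, VtoV, articulation rate (full precision, AR = 1000/VtoV),
#' interval counts and phonation time. When the sample's recording span
#' (phonation plus pauses and disfluencies) is shorter than `minDurationS`
#' the metrics are still computed but flagged as below the minimum reliable
#' duration, following the stabilization analysis that motivates the
#' 90 s default.
#'
#' @param sample a [SpeechSample-class].
#' @param minDurationS minimum reliable recording span in seconds
#'   (default 90).
#' @param chainPolicy passed to [vtov()].
#' @return a [RhythmMetrics-class] object.
#' @export
rhythmMetrics <- function(sample, minDurationS = 90,
                          chainPolicy = c("break", "concatenate")) {
  chainPolicy <- match.arg(chainPolicy)
  iv <- intervals(sample)
  counts <- table(factor(iv$label, levels = .VALID_LABELS))
  pv <- percentV(sample)
  vt <- vtov(sample, chainPolicy)
  new("RhythmMetrics",
      sampleId = sampleId(sample), year = recordingYear(sample),
      percentV = pv, vtovMs = vt$vtovMs,
      arSyllPerS = 1000 / vt$vtovMs,
      nV = as.integer(counts[["V"]]), nC = as.integer(counts[["C"]]),
      nD = as.integer(counts[["D"]]), nX = as.integer(counts[["X"]]),
      phonationS = phonationTime(sample),
      nVtoVIntervals = as.integer(vt$n),
      belowMinDuration = sampleSpan(sample) < minDurationS)
}

#' Metrics table for a list of samples
#'
#' Applies [rhythmMetrics()] to each sample and binds the one-row summaries.
#' Samples on which a metric is undefined are skipped with a warning and
#' reported in the `failures` attribute.
#'
#' @param samples list of [SpeechSample-class] objects.
#' @inheritParams rhythmMetrics
#' @return data.frame, one row per successful sample, with a `failures`
#'   attribute (character vector of sample ids, messages as names).
#' @export
metricsTable <- function(samples, minDurationS = 90,
                         chainPolicy = c("break", "concatenate")) {
  chainPolicy <- match.arg(chainPolicy)
  rows <- list()
  failures <- character(0)
  for (s in samples) {
    res <- tryCatch(as.data.frame(rhythmMetrics(s, minDurationS, chainPolicy)),
                    SpeechRhythm_error = function(e) e)
    if (inherits(res, "condition")) {
      failures[conditionMessage(res)] <- sampleId(s)
      srWarn("sampleSkipped", "sample '%s' skipped: %s",
             sampleId(s), conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(rhythmMetrics(sampleFromDurations(c(0.1, 0.1, 0.1),
                                                    c("V", "C", "V")),
                                minDurationS))[0, ]
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}
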