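#' @import methods
NULL

#' SpeechSample: an interval-labelled stretch of speech
#'
#' An ordered, non-overlapping sequence of timed intervals, each labelled
#' with one of the four codes used throughout the package:
#' \describe{
#'   \item{V}{vocalic interval}
#'   \item{C}{consonantal interval}
#'   \item{D}{disfluency (false start, vocalization, ...)}
#'   \item{X}{silent pause}
#' }
#' D and X intervals are annotated but excluded from the rhythm metrics.
#'
#' @slot sampleId character scalar identifying the sample.
#' @slot year integer recording year (NA when unknown).
#' @slot intervals data.frame with numeric columns `start`, `end` (seconds)
#'   and character column `label`.
#' @slot style free-text speech style (e.g. "interview"); NA when unknown.
#' @slot source free-text provenance; NA when unknown.
#'
#' @seealso [speechSample()], [readTextGrid()], [rhythmMetrics()]
#' @export
setClass("SpeechSample",
         representation(sampleId = "character",
                        year = "integer",
                        intervals = "data.frame",
                        style = "character",
                        source = "character"),
         prototype(sampleId = "sample",
                   year = NA_integer_,
                   intervals = data.frame(start = numeric(0),
                                          end = numeric(0),
                                          label = character(0),
                                          stringsAsFactors = FALSE),
                   style = NA_character_,
                   source = NA_character_))

setValidity("SpeechSample", function(object) {
  iv <- object@intervals
  msgs <- character(0)
  if (!all(c("start", "end", "label") %in% names(iv)))
    return("intervals must have columns start, end, label")
  if (length(object@sampleId) != 1L)
    msgs <- c(msgs, "sampleId must be a single string")
  if (length(object@year) != 1L)
    msgs <- c(msgs, "year must be a single integer")
  if (!is.na(object@year) && (object@year < 1900L || object@year > 2100L))
    msgs <- c(msgs, "year outside plausible range 1900-2100")
  if (nrow(iv) > 0L) {
    if (!is.numeric(iv$start) || !is.numeric(iv$end))
      return("interval times must be numeric seconds")
    bad <- which(iv$end <= iv$start)
    if (length(bad))
      msgs <- c(msgs, sprintf("interval %d has non-positive duration", bad[1L]))
    unk <- which(!(iv$label %in% .VALID_LABELS))
    if (length(unk))
      msgs <- c(msgs, sprintf("interval %d has label '%s' (must be V, C, D or X)",
                              unk[1L], iv$label[unk[1L]]))
    if (is.unsorted(iv$start))
      msgs <- c(msgs, "intervals must be sorted by start time")
    if (nrow(iv) > 1L) {
      ov <- which(iv$start[-1L] < iv$end[-nrow(iv)] - .TIME_TOL)
      if (length(ov))
        msgs <- c(msgs, sprintf("intervals %d and %d overlap", ov[1L], ov[1L] + 1L))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SpeechSample from interval vectors
#'
#' Labels are normalized (case-insensitive, surrounding whitespace stripped)
#' before validation; any token other than V, C, D or X is an error.
#'
#' @param start,end numeric vectors of interval boundaries in seconds.
#' @param label character vector of interval labels (V/C/D/X, any case).
#' @param sampleId sample identifier.
#' @param year recording year (integer or NA).
#' @param style,source optional free-text metadata.
#' @return A [SpeechSample-class] object.
#' @examples
#' s <- speechSample(c(0, 0.12, 0.2), c(0.12, 0.2, 0.3), c("V", "C", "V"))
#' phonationTime(s)
#' @export
speechSample <- function(start, end, label, sampleId = "sample",
                         year = NA_integer_, style = NA_character_,
                         source = NA_character_) {
  stopifnot(length(start) == length(end), length(end) == length(label))
  iv <- data.frame(start = as.numeric(start), end = as.numeric(end),
                   label = normalizeLabel(as.character(label)),
                   stringsAsFactors = FALSE)
  unk <- which(!(iv$label %in% .VALID_LABELS))
  if (length(unk))
    srStop("labellingError",
           "interval %d [%g, %g] has unknown label '%s'",
           unk[1L], iv$start[unk[1L]], iv$end[unk[1L]], label[unk[1L]])
  new("SpeechSample", sampleId = as.character(sampleId),
      year = as.integer(year), intervals = iv,
      style = as.character(style), source = as.character(source))
}

# Convenience used widely in tests and the generator: build a contiguous
# sample from durations, starting at time 0.
#' Build a contiguous SpeechSample from interval durations
#'
#' Intervals are laid end-to-end starting at 0 in the order given.
#'
#' @param durations numeric vector of interval durations in seconds.
#' @param labels character vector of labels (V/C/D/X).
#' @inheritParams speechSample
#' @return A [SpeechSample-class] object.
#' @export
sampleFromDurations <- function(durations, labels, sampleId = "sample",
                                year = NA_integer_, style = NA_character_,
                                source = NA_character_) {
  ends <- cumsum(as.numeric(durations))
  speechSample(c(0, ends[-length(ends)]), ends, labels,
               sampleId = sampleId, year = year, style = style,
               source = source)
}

#' RhythmMetrics: rhythm indexes for one speech sample
#'
#' Bundles the two rhythm indexes and their bookkeeping: %V (percentage of
#' vocalic duration over phonation time), VtoV (mean vowel-onset-to-onset
#' interval, ms), articulation rate (1000/VtoV, syllables/s), label counts,
#' phonation time, and a below-minimum-duration flag.
#'
#' @slot sampleId,year sample metadata carried through.
#' @slot percentV numeric, 0-100.
#' @slot vtovMs numeric, mean onset-to-onset interval in milliseconds.
#' @slot arSyllPerS numeric, articulation rate = 1000/vtovMs.
#' @slot nV,nC,nD,nX integer interval counts by label.
#' @slot phonationS numeric, summed V+C duration in seconds.
#' @slot nVtoVIntervals integer, onset-to-onset differences used for VtoV.
#' @slot belowMinDuration logical, TRUE when the sample span is shorter than
#'   the minimum reliable duration (default 90 s).
#' @export
setClass("RhythmMetrics",
         representation(sampleId = "character", year = "integer",
                        percentV = "numeric", vtovMs = "numeric",
                        arSyllPerS = "numeric",
                        nV = "integer", nC = "integer",
                        nD = "integer", nX = "integer",
                        phonationS = "numeric",
                        nVtoVIntervals = "integer",
                        belowMinDuration = "logical"))

setValidity("RhythmMetrics", function(object) {
  if (!is.na(object@percentV) &&
      (object@percentV < 0 || object@percentV > 100))
    return("percentV must lie in [0, 100]")
  if (!is.na(object@vtovMs) && object@nVtoVIntervals >= 1L &&
      object@vtovMs <= 0)
    return("vtovMs must be positive when defined")
  TRUE
})

#' StabilizationCurve: metrics over cumulative windows
#'
#' Metric values computed on prefixes of a sample truncated at window
#' lengths `stepS`, `2*stepS`, ... Window length is recording time
#' (pauses and disfluencies included); the metrics themselves still
#' exclude D and X.
#'
#' @slot sampleId sample the curve was computed from.
#' @slot stepS window increment in seconds.
#' @slot points data.frame with columns `windowS`, `percentV`, `vtovMs`
#'   (NA where a metric is undefined on a short prefix).
#' @export
setClass("StabilizationCurve",
         representation(sampleId = "character", stepS = "numeric",
                        points = "data.frame"))

setValidity("StabilizationCurve", function(object) {
  p <- object@points
  if (!all(c("windowS", "percentV", "vtovMs") %in% names(p)))
    return("points must have columns windowS, percentV, vtovMs")
  if (nrow(p) > 1L) {
    d <- diff(p$windowS)
    if (any(d <= 0)) return("window lengths must be strictly increasing")
    if (max(abs(d - object@stepS)) > .TIME_TOL)
      return("window lengths must increase in equal steps of stepS")
  }
  TRUE
})

#' StabilizationSummary: band-wise variability of a stabilization curve
#'
#' @slot bands data.frame with columns `loS`, `hiS`, `sdPercentV`,
#'   `sdVtovMs`, `nPoints`.
#' @slot recommendedMinS lower edge of the first band whose %V SD falls
#'   below the configured threshold (NA when no band qualifies).
#' @slot sdType "sample" (n-1) or "population" (n) SD convention used.
#' @export
setClass("StabilizationSummary",
         representation(bands = "data.frame", recommendedMinS = "numeric",
                        sdType = "character"))

#' PeriodPartition: a piecewise-constant split of a year series
#'
#' @slot breakYears numeric vector; each break year is the first year
#'   belonging to the new period.
#' @slot periods data.frame with columns `startYear`, `endYear`.
#' @slot rss residual sum of squares of the fitted segment means.
#' @slot improvement rss(no breaks) - rss (>= 0).
#' @export
setClass("PeriodPartition",
         representation(breakYears = "numeric", periods = "data.frame",
                        rss = "numeric", improvement = "numeric"))

setValidity("PeriodPartition", function(object) {
  b <- object@breakYears
  if (length(b) && is.unsorted(b, strictly = TRUE))
    return("breakYears must be strictly increasing")
  TRUE
})

#' PeriodComparison: per-period summaries and pairwise t-tests
#'
#' @slot summaries data.frame with one row per period: `period`,
#'   `startYear`, `endYear`, `n`, `mean`, `sd`, `min`, `max`.
#' @slot tests data.frame with one row per compared pair: `periodA`,
#'   `periodB`, `t`, `df`, `pValue`, `significant` (at the configured alpha).
#' @slot test "welch" or "pooled".
#' @slot alpha significance level used for the `significant` flag.
#' @export
setClass("PeriodComparison",
         representation(summaries = "data.frame", tests = "data.frame",
                        test = "character", alpha = "numeric"))

setValidity("PeriodComparison", function(object) {
  p <- object@tests$pValue
  if (length(p) && any(!is.na(p) & (p < 0 | p > 1)))
    return("p-values must lie in [0, 1]")
  TRUE
})

#' GeneratorConfig: parameters of the synthetic interval-sequence generator
#'
#' Interval durations are gamma-distributed with means chosen so that,
#' without pauses, the expected %V and expected vowel-onset interval hit
#' `targetPercentV` and `targetVtovMs` exactly:
#' E\[V\] = (targetPercentV/100) * VtoV and E\[C\] = VtoV - E\[V\].
#'
#' @slot targetPercentV target %V (0-100, exclusive).
#' @slot targetVtovMs target mean onset-to-onset interval, ms.
#' @slot durationS recording span to generate, seconds.
#' @slot durationCv coefficient of variation of interval durations
#'   (0 gives deterministic durations).
#' @slot pauseRatePerS expected silent pauses (X) per second of phonation.
#' @slot pauseMeanS mean pause duration, seconds (minimum 0.25 s, the
#'   conventional silent-pause floor).
#' @slot disfluencyRatePerS expected disfluencies (D) per second of phonation.
#' @slot disfluencyMeanS mean disfluency duration, seconds.
#' @slot seed integer RNG seed; identical seeds give identical samples.
#' @export
setClass("GeneratorConfig",
         representation(targetPercentV = "numeric", targetVtovMs = "numeric",
                        durationS = "numeric", durationCv = "numeric",
                        pauseRatePerS = "numeric", pauseMeanS = "numeric",
                        disfluencyRatePerS = "numeric",
                        disfluencyMeanS = "numeric", seed = "integer"),
         prototype(targetPercentV = 45.3, targetVtovMs = 196,
                   durationS = 120, durationCv = 0.4,
                   pauseRatePerS = 0.05, pauseMeanS = 0.8,
                   disfluencyRatePerS = 0.01, disfluencyMeanS = 0.3,
                   seed = 1L))

setValidity("GeneratorConfig", function(object) {
  msgs <- character(0)
  if (object@targetPercentV <= 0 || object@targetPercentV >= 100)
    msgs <- c(msgs, "targetPercentV must lie strictly between 0 and 100")
  if (object@targetVtovMs <= 0) msgs <- c(msgs, "targetVtovMs must be positive")
  if (object@durationS <= 0) msgs <- c(msgs, "durationS must be positive")
  if (object@durationCv < 0) msgs <- c(msgs, "durationCv must be >= 0")
  if (object@pauseRatePerS < 0) msgs <- c(msgs, "pauseRatePerS must be >= 0")
  if (object@pauseMeanS < 0.25)
    msgs <- c(msgs, "pauseMeanS must be >= 0.25 s")
  if (object@disfluencyRatePerS < 0)
    msgs <- c(msgs, "disfluencyRatePerS must be >= 0")
  if (object@disfluencyMeanS <= 0)
    msgs <- c(msgs, "disfluencyMeanS must be positive")
  if (length(msgs)) msgs else TRUE
})

#' TrajectoryParams: parameters of the synthetic longitudinal corpus
#'
#' Per-sample target %V follows a piecewise-constant staircase over periods
#' delimited by `breakYears` (each break year starts a new period), with
#' normal year-to-year fluctuation at the per-period SD; target VtoV drifts
#' linearly from `vtovStartMs` to `vtovEndMs` across the year range.
#'
#' @slot years integer vector of recording years.
#' @slot samplesPerYear samples generated per year.
#' @slot periodMeansPercentV mean %V per period (length = breaks + 1).
#' @slot periodSdsPercentV SD of per-sample target %V per period.
#' @slot breakYears first year of each new period.
#' @slot vtovStartMs,vtovEndMs endpoints of the linear VtoV drift.
#' @slot diagnosisYear reference year used to annotate reports
#'   ("years before diagnosis"); metadata only, never inferred.
#' @slot sampleDurationS recording span of each generated sample, seconds.
#' @slot pauseRatePerS,disfluencyRatePerS,durationCv passed through to
#'   [generatorConfig()].
#' @export
setClass("TrajectoryParams",
         representation(years = "integer", samplesPerYear = "integer",
                        periodMeansPercentV = "numeric",
                        periodSdsPercentV = "numeric",
                        breakYears = "numeric",
                        vtovStartMs = "numeric", vtovEndMs = "numeric",
                        diagnosisYear = "numeric",
                        sampleDurationS = "numeric",
                        pauseRatePerS = "numeric",
                        disfluencyRatePerS = "numeric",
                        durationCv = "numeric"),
         prototype(years = 1979:2021, samplesPerYear = 1L,
                   periodMeansPercentV = c(45.3, 48.8, 50.3),
                   periodSdsPercentV = c(0.87, 0.85, 0.37),
                   breakYears = c(2010, 2015),
                   vtovStartMs = 196, vtovEndMs = 224,
                   diagnosisYear = 2015, sampleDurationS = 120,
                   pauseRatePerS = 0.05, disfluencyRatePerS = 0.01,
                   durationCv = 0.4))

setValidity("TrajectoryParams", function(object) {
  msgs <- character(0)
  k <- length(object@breakYears)
  if (length(object@periodMeansPercentV) != k + 1L)
    msgs <- c(msgs, "need one period mean per period (breaks + 1)")
  if (length(object@periodSdsPercentV) != k + 1L)
    msgs <- c(msgs, "need one period SD per period (breaks + 1)")
  if (any(object@periodSdsPercentV <= 0))
    msgs <- c(msgs, "period SDs must be positive")
  if (k && (min(object@breakYears) <= min(object@years) ||
            max(object@breakYears) > max(object@years)))
    msgs <- c(msgs, "breakYears must fall inside the year range")
  if (k > 1L && is.unsorted(object@breakYears, strictly = TRUE))
    msgs <- c(msgs, "breakYears must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' SegmenterConfig: parameters of the acoustic V/C/X segmenter
#'
#' @slot frameS analysis frame length, seconds.
#' @slot hopS frame hop, seconds (frameS >= hopS).
#' @slot silenceFloorDb absolute silence floor in dB re full scale; the
#'   effective threshold is the larger of this and noise floor + 10 dB.
#' @slot periodicityThreshold minimum normalized autocorrelation peak for a
#'   frame to count as vocalic.
#' @slot flatnessThreshold maximum spectral flatness for a vocalic frame.
#' @slot minPauseS silences shorter than this are treated as consonantal
#'   closures, not pauses (default 0.25 s, the phonetics convention).
#' @slot minIntervalS intervals shorter than this are merged into the longer
#'   neighbour.
#' @slot medianFilterFrames width (frames, odd) of the label smoothing filter.
#' @slot f0MinHz,f0MaxHz pitch search range for the periodicity feature.
#' @export
setClass("SegmenterConfig",
         representation(frameS = "numeric", hopS = "numeric",
                        silenceFloorDb = "numeric",
                        periodicityThreshold = "numeric",
                        flatnessThreshold = "numeric",
                        minPauseS = "numeric", minIntervalS = "numeric",
                        medianFilterFrames = "integer",
                        f0MinHz = "numeric", f0MaxHz = "numeric"),
         prototype(frameS = 0.025, hopS = 0.010, silenceFloorDb = -60,
                   periodicityThreshold = 0.45, flatnessThreshold = 0.3,
                   minPauseS = 0.25, minIntervalS = 0.02,
                   medianFilterFrames = 5L, f0MinHz = 60, f0MaxHz = 400))

setValidity("SegmenterConfig", function(object) {
  msgs <- character(0)
  if (object@frameS < object@hopS)
    msgs <- c(msgs, "frameS must be >= hopS")
  if (any(c(object@frameS, object@hopS, object@minPauseS,
            object@minIntervalS) <= 0))
    msgs <- c(msgs, "durations must be positive")
  if (object@medianFilterFrames %% 2L == 0L)
    msgs <- c(msgs, "medianFilterFrames must be odd")
  if (object@f0MinHz >= object@f0MaxHz)
    msgs <- c(msgs, "f0MinHz must be < f0MaxHz")
  if (length(msgs)) msgs else TRUE
})

#' FrameFeatures: per-frame acoustic features for segmentation
#'
#' @slot times frame centre times, seconds.
#' @slot energyDb per-frame RMS energy in dB re full scale.
#' @slot periodicity normalized autocorrelation peak in the pitch lag range.
#' @slot flatness spectral flatness (geometric/arithmetic mean of power).
#' @slot sampleRate,frameS,hopS analysis geometry, recorded for traceability.
#' @export
setClass("FrameFeatures",
         representation(times = "numeric", energyDb = "numeric",
                        periodicity = "numeric", flatness = "numeric",
                        sampleRate = "numeric", frameS = "numeric",
                        hopS = "numeric"))

setValidity("FrameFeatures", function(object) {
  n <- length(object@times)
  if (length(object@energyDb) != n || length(object@periodicity) != n ||
      length(object@flatness) != n)
    return("feature tracks must have equal length")
  TRUE
})
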