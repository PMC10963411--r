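# Prototype text-independent acoustic segmenter: label audio into vocalic
# (V), consonantal (C) and silent (X) intervals from frame-level features,
# then compute rhythm metrics. The feature rationale mirrors how the two
# classes look on a spectrogram: vowels are periodic and formant-structured
# (high autocorrelation, low spectral flatness), obstruents are silent or
# noise-like (low energy, or aperiodic with a flat spectrum).
#
# This is an engineering prototype validated on schematic synthetic audio
# where ground truth exists; no accuracy claim is made for natural speech.

#' Construct a SegmenterConfig
#'
#' See [SegmenterConfig-class] for parameter meanings and defaults.
#'
#' @param frameS,hopS,silenceFloorDb,periodicityThreshold,flatnessThreshold,minPauseS,minIntervalS,medianFilterFrames,f0MinHz,f0MaxHz see [SegmenterConfig-class].
#' @return a validated [SegmenterConfig-class].
#' @export
segmenterConfig <- function(frameS = 0.025, hopS = 0.010,
                            silenceFloorDb = -60,
                            periodicityThreshold = 0.45,
                            flatnessThreshold = 0.3, minPauseS = 0.25,
                            minIntervalS = 0.02, medianFilterFrames = 5L,
                            f0MinHz = 60, f0MaxHz = 400) {
  new("SegmenterConfig", frameS = frameS, hopS = hopS,
      silenceFloorDb = silenceFloorDb,
      periodicityThreshold = periodicityThreshold,
      flatnessThreshold = flatnessThreshold, minPauseS = minPauseS,
      minIntervalS = minIntervalS,
      medianFilterFrames = as.integer(medianFilterFrames),
      f0MinHz = f0MinHz, f0MaxHz = f0MaxHz)
}

#' Extract frame-level features for V/C/X classification
#'
#' Per frame: RMS energy (dB re full scale), the normalized autocorrelation
#' peak in the pitch lag range (periodicity), and spectral flatness
#' (geometric over arithmetic mean of the power spectrum). FFTs are batched
#' over frames; autocorrelation is obtained from the same transforms.
#'
#' @param wave numeric mono waveform in \[-1, 1\].
#' @param sampleRate sampling rate in Hz (>= 8000).
#' @param config a [SegmenterConfig-class].
#' @return a [FrameFeatures-class].
#' @export
extractFeatures <- function(wave, sampleRate, config = segmenterConfig()) {
  stopifnot(is(config, "SegmenterConfig"))
  if (!is.numeric(wave) || length(wave) == 0L)
    srStop("emptyInput", "waveform is empty or not numeric")
  if (is.matrix(wave) && ncol(wave) > 1L)
    srStop("badInput", "only mono waveforms are supported")
  if (sampleRate < 8000)
    srStop("badInput", "sample rate must be at least 8 kHz")
  frameLen <- round(config@frameS * sampleRate)
  hop <- round(config@hopS * sampleRate)
  if (length(wave) < frameLen)
    srStop("emptyInput", "waveform shorter than one analysis frame")
  starts <- seq.int(1L, length(wave) - frameLen + 1L, by = hop)
  nFrames <- length(starts)
  nfft <- 2^ceiling(log2(frameLen * 2))
  lagLo <- max(2L, floor(sampleRate / config@f0MaxHz))
  lagHi <- min(frameLen - 1L, ceiling(sampleRate / config@f0MinHz))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(frameLen) / (frameLen + 1))
  binSel <- 2:(nfft / 2)   # exclude DC and mirror half
  eps <- 1e-12

  energy <- periodicity <- flatness <- numeric(nFrames)
  blockSize <- 2048L
  for (b0 in seq.int(1L, nFrames, by = blockSize)) {
    idx <- b0:min(b0 + blockSize - 1L, nFrames)
    frames <- matrix(wave[outer(0:(frameLen - 1L), starts[idx], `+`)],
                     nrow = frameLen)
    energy[idx] <- sqrt(colMeans(frames^2))
    # windowed transform for the flatness spectrum
    padded <- matrix(0, nrow = nfft, ncol = length(idx))
    padded[seq_len(frameLen), ] <- frames * win
    power <- Mod(stats::mvfft(padded))^2
    ps <- power[binSel, , drop = FALSE]
    flatness[idx] <- exp(colMeans(log(ps + eps))) / (colMeans(ps) + eps)
    # unwindowed transform for the (linear, zero-padded) autocorrelation;
    # unbiased lag scaling so a periodic frame scores near 1
    padded[seq_len(frameLen), ] <- frames
    acPower <- Mod(stats::mvfft(padded))^2
    ac <- Re(stats::mvfft(acPower, inverse = TRUE)) / nfft
    r0 <- ac[1L, ]
    lags <- lagLo:lagHi
    unbias <- frameLen / (frameLen - lags)
    acn <- ac[lags + 1L, , drop = FALSE] * unbias
    peak <- apply(acn, 2L, max)
    periodicity[idx] <- pmax(0, pmin(1, peak / pmax(r0, eps)))
  }
  new("FrameFeatures",
      times = (starts - 1 + frameLen / 2) / sampleRate,
      energyDb = 20 * log10(energy + 1e-10),
      periodicity = periodicity, flatness = flatness,
      sampleRate = sampleRate, frameS = config@frameS, hopS = config@hopS)
}

# Majority-vote smoothing of a 3-class label track. Ties go to the class
# listed first in X < C < V priority only via deterministic max.col order;
# the window is centred and shrinks at the edges.
.majoritySmooth <- function(labels, width) {
  if (width <= 1L || length(labels) < 3L) return(labels)
  classes <- c("V", "C", "X")
  ind <- outer(labels, classes, `==`) * 1
  kern <- rep(1, width)
  counts <- apply(ind, 2L, function(col)
    as.numeric(stats::filter(col, kern, sides = 2)))
  counts <- matrix(counts, ncol = 3L)
  # shrink window at edges: recompute the NA margins directly
  half <- (width - 1L) %/% 2L
  n <- length(labels)
  for (i in c(seq_len(half), n - seq_len(half) + 1L)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    counts[i, ] <- colSums(ind[lo:hi, , drop = FALSE])
  }
  classes[max.col(counts, ties.method = "first")]
}

#' Classify feature frames as V, C or X
#'
#' A frame is silent (X) when its energy falls below the silence threshold:
#' the larger of the absolute floor (`silenceFloorDb`, dB re full scale) and
#' the estimated noise floor (5th energy percentile) + 10 dB. A non-silent
#' frame is vocalic (V) when periodicity is at or above the periodicity
#' threshold and flatness at or below the flatness threshold, else
#' consonantal (C). The label track is then smoothed with a centred
#' majority filter.
#'
#' @param features a [FrameFeatures-class].
#' @param config a [SegmenterConfig-class].
#' @return character vector of frame labels in `{V, C, X}`.
#' @export
classifyFrames <- function(features, config = segmenterConfig()) {
  stopifnot(is(features, "FrameFeatures"))
  e <- features@energyDb
  noiseFloor <- stats::quantile(e, 0.05, names = FALSE)
  thr <- max(config@silenceFloorDb, noiseFloor + 10)
  # guard: never let the adaptive part silence the upper half of the energy
  # distribution (recordings with no silence at all)
  thr <- min(thr, stats::quantile(e, 0.5, names = FALSE) - 3)
  thr <- max(thr, config@silenceFloorDb)
  labels <- ifelse(e < thr, "X",
                   ifelse(features@periodicity >= config@periodicityThreshold &
                          features@flatness <= config@flatnessThreshold,
                          "V", "C"))
  .majoritySmooth(labels, config@medianFilterFrames)
}

#' Merge labelled frames into a SpeechSample
#'
#' Consecutive equal labels are merged into intervals whose boundaries lie
#' midway between neighbouring frame centres. Intervals shorter than
#' `minIntervalS` are absorbed into the longer neighbour; X intervals
#' shorter than `minPauseS` are relabelled C (sub-threshold silences are
#' treated as stop closures, not pauses).
#'
#' @param labels character vector of frame labels (V/C/X).
#' @param features the [FrameFeatures-class] the labels came from (supplies
#'   the time base).
#' @param config a [SegmenterConfig-class].
#' @param totalDurationS span of the underlying audio in seconds; defaults
#'   to the last frame's right edge.
#' @param sampleId id for the resulting sample.
#' @return a [SpeechSample-class].
#' @export
framesToIntervals <- function(labels, features, config = segmenterConfig(),
                              totalDurationS = NULL, sampleId = "segmented") {
  stopifnot(length(labels) == length(features@times))
  times <- features@times
  n <- length(labels)
  if (is.null(totalDurationS))
    totalDurationS <- times[n] + features@frameS / 2
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  startsIdx <- ends - r$lengths + 1L
  bStart <- ifelse(startsIdx == 1L, 0,
                   (times[pmax(startsIdx - 1L, 1L)] + times[startsIdx]) / 2)
  bEnd <- ifelse(ends == n, totalDurationS,
                 (times[ends] + times[pmin(ends + 1L, n)]) / 2)
  iv <- data.frame(start = bStart, end = bEnd, label = r$values,
                   stringsAsFactors = FALSE)

  mergeAdjacent <- function(iv) {
    if (nrow(iv) < 2L) return(iv)
    same <- c(FALSE, iv$label[-1L] == iv$label[-nrow(iv)])
    grp <- cumsum(!same)
    data.frame(start = tapply(iv$start, grp, min),
               end = tapply(iv$end, grp, max),
               label = tapply(iv$label, grp, `[`, 1L),
               stringsAsFactors = FALSE, row.names = NULL)
  }

  # absorb sub-minimum intervals into the longer neighbour, repeatedly
  repeat {
    dur <- iv$end - iv$start
    short <- which(dur < config@minIntervalS - .TIME_TOL)
    short <- short[!(short %in% c(0L))]
    if (!length(short) || nrow(iv) < 2L) break
    i <- short[which.min(dur[short])]
    left <- if (i > 1L) dur[i - 1L] else -Inf
    right <- if (i < nrow(iv)) dur[i + 1L] else -Inf
    into <- if (left >= right) i - 1L else i + 1L
    iv$label[i] <- iv$label[into]
    iv <- mergeAdjacent(iv)
  }
  # sub-threshold silences are closures, not pauses
  isShortX <- iv$label == "X" &
    (iv$end - iv$start) < config@minPauseS - .TIME_TOL
  iv$label[isShortX] <- "C"
  iv <- mergeAdjacent(iv)
  speechSample(iv$start, iv$end, iv$label, sampleId = sampleId)
}

#' Segment audio into V/C/X intervals and compute rhythm metrics
#'
#' End-to-end prototype of a rhythm "speech test": features, frame
#' classification, interval construction, then [rhythmMetrics()] including
#' the below-minimum-duration flag (90 s by default). Identical audio gives
#' identical segmentations.
#'
#' @param wave numeric mono waveform in \[-1, 1\].
#' @param sampleRate sampling rate in Hz.
#' @param config a [SegmenterConfig-class].
#' @param minDurationS minimum reliable duration passed to
#'   [rhythmMetrics()].
#' @param sampleId id for the resulting sample.
#' @return list with `sample` (a [SpeechSample-class]) and `metrics`
#'   (a [RhythmMetrics-class]).
#' @export
segmentAudio <- function(wave, sampleRate, config = segmenterConfig(),
                         minDurationS = 90, sampleId = "segmented") {
  features <- extractFeatures(wave, sampleRate, config)
  labels <- classifyFrames(features, config)
  sample <- framesToIntervals(labels, features, config,
                              totalDurationS = length(wave) / sampleRate,
                              sampleId = sampleId)
  metrics <- rhythmMetrics(sample, minDurationS = minDurationS)
  list(sample = sample, metrics = metrics)
}
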