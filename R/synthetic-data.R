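# Synthetic speech-interval data with known ground truth: single samples,
# longitudinal corpora with a step change in %V, and schematic audio.
#
# Durations are gamma-distributed. With target %V = p and target VtoV = m,
# E[V] = p*m and E[C] = (1-p)*m, so that without pauses both the expected
# vocalic proportion and the expected vowel-onset interval hit their targets.

#' Construct a GeneratorConfig
#'
#' See [GeneratorConfig-class] for the meaning and defaults of each
#' parameter. Defaults are calibrated to the pre-change period of the
#' longitudinal corpus the package models (%V 45.3, VtoV 196 ms).
#'
#' @param targetPercentV,targetVtovMs,durationS,durationCv,pauseRatePerS,pauseMeanS,disfluencyRatePerS,disfluencyMeanS,seed see [GeneratorConfig-class].
#' @return a validated [GeneratorConfig-class].
#' @export
generatorConfig <- function(targetPercentV = 45.3, targetVtovMs = 196,
                            durationS = 120, durationCv = 0.4,
                            pauseRatePerS = 0.05, pauseMeanS = 0.8,
                            disfluencyRatePerS = 0.01,
                            disfluencyMeanS = 0.3, seed = 1L) {
  new("GeneratorConfig", targetPercentV = targetPercentV,
      targetVtovMs = targetVtovMs, durationS = durationS,
      durationCv = durationCv, pauseRatePerS = pauseRatePerS,
      pauseMeanS = pauseMeanS, disfluencyRatePerS = disfluencyRatePerS,
      disfluencyMeanS = disfluencyMeanS, seed = as.integer(seed))
}

# Gamma draws with given mean and CV; CV 0 degenerates to the mean.
.rdur <- function(n, mean, cv) {
  if (n == 0L) return(numeric(0))
  if (cv <= 1e-12) return(rep(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

# Pause/disfluency durations: a hard floor plus an exponential tail keeps
# the mean while respecting the minimum.
.rgap <- function(n, mean, floor) {
  if (n == 0L) return(numeric(0))
  if (mean <= floor + 1e-12) return(rep(floor, n))
  floor + stats::rexp(n, 1 / (mean - floor))
}

#' Generate a synthetic interval-labelled speech sample
#'
#' Builds a strictly alternating V/C sequence with gamma-distributed
#' durations, optionally interleaved with silent pauses (X) and
#' disfluencies (D) inserted at C-to-V boundaries as Poisson processes over
#' phonation time. Generation stops once the recording span reaches
#' `durationS`. Identical seeds give identical samples.
#'
#' @param config a [GeneratorConfig-class] (see [generatorConfig()]).
#' @param sampleId,year,style metadata for the resulting sample.
#' @return a [SpeechSample-class] starting with a V interval at time 0.
#' @export
generateSample <- function(config = generatorConfig(),
                           sampleId = "synthetic", year = NA_integer_,
                           style = "synthetic") {
  stopifnot(is(config, "GeneratorConfig"))
  validObject(config)
  set.seed(config@seed)
  p <- config@targetPercentV / 100
  m <- config@targetVtovMs / 1000
  # overdraw pairs; pauses only lengthen the span, so this bound suffices
  nPairs <- ceiling(config@durationS / m * 1.2) + 20L
  vDur <- .rdur(nPairs, p * m, config@durationCv)
  cDur <- .rdur(nPairs, (1 - p) * m, config@durationCv)
  pairDur <- vDur + cDur
  # Poisson thinning per phonation stretch: P(event) = 1 - exp(-rate * dur)
  dHit <- stats::runif(nPairs) < 1 - exp(-config@disfluencyRatePerS * pairDur)
  xHit <- stats::runif(nPairs) < 1 - exp(-config@pauseRatePerS * pairDur)
  dDur <- .rgap(nPairs, config@disfluencyMeanS, 0.05)
  xDur <- .rgap(nPairs, config@pauseMeanS, 0.25)
  dDur[!dHit] <- 0
  xDur[!xHit] <- 0

  # assemble per pair: V, C, [D], [X]
  per <- 2L + dHit + xHit
  total <- sum(per)
  labels <- character(total)
  durs <- numeric(total)
  pos <- cumsum(c(1L, per[-nPairs]))
  labels[pos] <- "V";          durs[pos] <- vDur
  labels[pos + 1L] <- "C";     durs[pos + 1L] <- cDur
  dPos <- pos[dHit] + 2L
  labels[dPos] <- "D";         durs[dPos] <- dDur[dHit]
  xPos <- pos[xHit] + 2L + dHit[xHit]
  labels[xPos] <- "X";         durs[xPos] <- xDur[xHit]

  spanEnd <- cumsum(durs)
  nKeep <- which(spanEnd >= config@durationS)[1L]
  if (is.na(nKeep)) nKeep <- total   # target span not reached; keep all
  labels <- labels[seq_len(nKeep)]
  durs <- durs[seq_len(nKeep)]
  sampleFromDurations(durs, labels, sampleId = sampleId, year = year,
                      style = style, source = "generator")
}

#' Construct TrajectoryParams for a synthetic longitudinal corpus
#'
#' Defaults describe a 43-year corpus (1979-2021) whose %V staircase rises
#' from a 45.3 baseline to 48.8 at the 2010 changepoint (five years before
#' the nominal 2015 diagnosis year) and 50.3 from 2015 on, with per-period
#' SDs 0.87/0.85/0.37, while VtoV drifts linearly from 196 to 224 ms.
#'
#' @param years,samplesPerYear,periodMeansPercentV,periodSdsPercentV,breakYears,vtovStartMs,vtovEndMs,diagnosisYear,sampleDurationS,pauseRatePerS,disfluencyRatePerS,durationCv see [TrajectoryParams-class].
#' @return a validated [TrajectoryParams-class].
#' @export
trajectoryParams <- function(years = 1979:2021, samplesPerYear = 1L,
                             periodMeansPercentV = c(45.3, 48.8, 50.3),
                             periodSdsPercentV = c(0.87, 0.85, 0.37),
                             breakYears = c(2010, 2015),
                             vtovStartMs = 196, vtovEndMs = 224,
                             diagnosisYear = 2015, sampleDurationS = 120,
                             pauseRatePerS = 0.05,
                             disfluencyRatePerS = 0.01, durationCv = 0.4) {
  new("TrajectoryParams", years = as.integer(years),
      samplesPerYear = as.integer(samplesPerYear),
      periodMeansPercentV = periodMeansPercentV,
      periodSdsPercentV = periodSdsPercentV,
      breakYears = as.numeric(breakYears),
      vtovStartMs = vtovStartMs, vtovEndMs = vtovEndMs,
      diagnosisYear = diagnosisYear, sampleDurationS = sampleDurationS,
      pauseRatePerS = pauseRatePerS,
      disfluencyRatePerS = disfluencyRatePerS, durationCv = durationCv)
}

#' Generate a synthetic longitudinal corpus
#'
#' For each year and sample, draws a target %V from the year's period mean
#' and SD, interpolates the target VtoV linearly across the year range, and
#' generates a [SpeechSample-class] via [generateSample()]. Returns the
#' samples together with a corpus manifest.
#'
#' @param params a [TrajectoryParams-class] (see [trajectoryParams()]).
#' @param seed integer seed controlling all randomness.
#' @return list with `samples` (named list of SpeechSample), `manifest`
#'   (data.frame: `sample_id`, `year`, `annotation_path` (NA until
#'   written), `style`, `target_percent_v`, `target_vtov_ms`) and
#'   `params`.
#' @export
generateCorpus <- function(params = trajectoryParams(), seed = 1L) {
  stopifnot(is(params, "TrajectoryParams"))
  validObject(params)
  set.seed(seed)
  years <- params@years
  yrRange <- range(years)
  frac <- if (diff(yrRange) > 0) (years - yrRange[1L]) / diff(yrRange)
          else rep(0, length(years))
  vtovByYear <- params@vtovStartMs + frac * (params@vtovEndMs - params@vtovStartMs)
  period <- findInterval(years, params@breakYears) + 1L
  samples <- list()
  rows <- list()
  for (i in seq_along(years)) {
    for (j in seq_len(params@samplesPerYear)) {
      target <- stats::rnorm(1, params@periodMeansPercentV[period[i]],
                             params@periodSdsPercentV[period[i]])
      target <- min(max(target, 1), 99)
      subseed <- sample.int(.Machine$integer.max - 1L, 1L)
      id <- sprintf("y%d_s%02d", years[i], j)
      cfg <- generatorConfig(targetPercentV = target,
                             targetVtovMs = vtovByYear[i],
                             durationS = params@sampleDurationS,
                             durationCv = params@durationCv,
                             pauseRatePerS = params@pauseRatePerS,
                             disfluencyRatePerS = params@disfluencyRatePerS,
                             seed = subseed)
      samples[[id]] <- generateSample(cfg, sampleId = id, year = years[i])
      rows[[length(rows) + 1L]] <-
        data.frame(sample_id = id, year = years[i],
                   annotation_path = NA_character_, style = "synthetic",
                   target_percent_v = target,
                   target_vtov_ms = vtovByYear[i],
                   stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  list(samples = samples, manifest = manifest, params = params)
}
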