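# Orchestration layer: the run* functions behind the command-line interface
# (inst/cli/speechrhythm.R). Each takes file paths plus the analysis
# parameters (defaults: 90 s minimum duration, 10 s stabilization steps,
# k = 2 breakpoints, Welch tests, alpha 0.05) and writes plain-text
# outputs (CSV, JSON, TextGrid, WAV). Reports carry no timestamps, so a
# given input and seed reproduce byte-identical files.

.writeReport <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Compute the metrics table for a corpus manifest
#'
#' Reads each annotation listed in the manifest, computes rhythm metrics,
#' and collects one row per sample. Files that fail to parse or yield
#' undefined metrics are skipped and reported; `status` is 0 when all
#' samples succeeded, 2 on partial failure.
#'
#' @param manifestPath path to a corpus manifest CSV
#'   (see [readCorpusTable()]).
#' @param tier TextGrid tier name holding the V/C/D/X labels.
#' @param minDurationS minimum reliable duration flag threshold (s).
#' @param outPath optional CSV path for the metrics table.
#' @return list with `table` (metrics data.frame including `year`),
#'   `failures` (named character vector), `status` (0 or 2).
#' @export
runMetrics <- function(manifestPath, tier = "segments", minDurationS = 90,
                       outPath = NULL) {
  manifest <- readCorpusTable(manifestPath)
  base <- dirname(manifestPath)
  rows <- list()
  failures <- character(0)
  for (i in seq_len(nrow(manifest))) {
    path <- manifest$annotation_path[i]
    if (!file.exists(path) && file.exists(file.path(base, path)))
      path <- file.path(base, path)
    res <- tryCatch({
      s <- readTextGrid(path, tier = tier,
                        sampleId = manifest$sample_id[i],
                        year = manifest$year[i])
      as.data.frame(rhythmMetrics(s, minDurationS = minDurationS))
    }, SpeechRhythm_error = function(e) e, error = function(e) e)
    if (inherits(res, "condition")) {
      failures[manifest$sample_id[i]] <- conditionMessage(res)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(tab)) rownames(tab) <- NULL
  if (!is.null(outPath) && !is.null(tab))
    utils::write.csv(tab, outPath, row.names = FALSE, quote = FALSE)
  list(table = tab, failures = failures,
       status = if (length(failures)) 2L else 0L)
}

#' Longitudinal changepoint report for a metrics table
#'
#' Builds the year-by-year metric series, fits the k-breakpoint
#' least-squares partition, summarizes the periods and runs the pairwise
#' t-tests. When `diagnosisYear` is given, each breakpoint is annotated
#' with its lead relative to diagnosis (breakYear - diagnosisYear,
#' negative = before diagnosis).
#'
#' @param table metrics data.frame (from [runMetrics()] or
#'   [metricsTable()]), or the path of a metrics CSV.
#' @param metric metric column to analyse (default `"percent_v"`).
#' @param k number of breakpoints (default 2).
#' @param test `"welch"` (default) or `"pooled"`.
#' @param alpha significance level (default 0.05).
#' @param diagnosisYear optional reference year (metadata, never inferred).
#' @param outJson optional path for the JSON report.
#' @return the report as a list (invisibly written to `outJson` when
#'   given): `metric`, `partition`, `periods`, `tests`,
#'   `anySignificantChange`, and optionally `yearsBeforeDiagnosis`.
#' @export
runLongitudinal <- function(table, metric = "percent_v", k = 2L,
                            test = c("welch", "pooled"), alpha = 0.05,
                            diagnosisYear = NULL, outJson = NULL) {
  test <- match.arg(test)
  if (is.character(table)) table <- utils::read.csv(table)
  series <- metricSeries(table, metric)
  partition <- findChangepoints(series, k = k)
  comparison <- comparePeriods(series, partition, test = test, alpha = alpha)
  report <- list(
    metric = metric,
    k = as.integer(k),
    test = test,
    alpha = alpha,
    partition = list(breakYears = partition@breakYears,
                     periods = partition@periods,
                     rss = partition@rss,
                     improvement = partition@improvement),
    periods = comparison@summaries,
    tests = comparison@tests,
    anySignificantChange = any(comparison@tests$significant))
  if (!is.null(diagnosisYear))
    report$yearsBeforeDiagnosis <- partition@breakYears - diagnosisYear
  if (!is.null(outJson)) .writeReport(report, outJson)
  report
}

#' Stabilization report for a single annotated sample
#'
#' @param input a [SpeechSample-class] or the path of a TextGrid.
#' @param tier tier name (when `input` is a path).
#' @param stepS window increment in seconds (default 10).
#' @param outCsv optional path for the curve (`window_s,percent_v,vtov_ms`).
#' @param outJson optional path for the band summary JSON.
#' @inheritParams bandSummary
#' @return list with `curve` (a [StabilizationCurve-class]) and `summary`
#'   (a [StabilizationSummary-class]).
#' @export
runStabilize <- function(input, tier = "segments", stepS = 10,
                         bands = .DEFAULT_BANDS, sdThresholdPercentV = 0.5,
                         sdType = c("sample", "population"),
                         outCsv = NULL, outJson = NULL) {
  sdType <- match.arg(sdType)
  sample <- if (is(input, "SpeechSample")) input else readTextGrid(input, tier)
  curve <- stabilizationCurve(sample, stepS = stepS)
  summary <- bandSummary(curve, bands, sdThresholdPercentV, sdType)
  if (!is.null(outCsv)) {
    p <- curvePoints(curve)
    names(p) <- c("window_s", "percent_v", "vtov_ms")
    utils::write.csv(p, outCsv, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(outJson))
    .writeReport(list(sample_id = sampleId(sample), step_s = stepS,
                      sd_type = sdType, bands = summary@bands,
                      recommended_min_s = summary@recommendedMinS), outJson)
  list(curve = curve, summary = summary)
}

#' Generate a synthetic corpus on disk
#'
#' Writes one ground-truth TextGrid per sample plus a `manifest.csv`;
#' optionally renders schematic audio as WAV alongside each annotation.
#'
#' @param outDir output directory (created if missing).
#' @param params a [TrajectoryParams-class]; the default is the package's
#'   longitudinal preset (43 years, %V staircase 45.3/48.8/50.3 with
#'   breaks at 2010 and 2015).
#' @param seed integer seed.
#' @param audio also write WAV renderings (slow for large corpora).
#' @param sampleRate audio sampling rate when `audio = TRUE`.
#' @return the manifest data.frame (with `annotation_path` and, when
#'   rendered, `audio_path` filled in), invisibly.
#' @export
runSimulate <- function(outDir, params = trajectoryParams(), seed = 1L,
                        audio = FALSE, sampleRate = 16000) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  corpus <- generateCorpus(params, seed = seed)
  manifest <- corpus$manifest
  manifest$annotation_path <- paste0(manifest$sample_id, ".TextGrid")
  if (audio) manifest$audio_path <- paste0(manifest$sample_id, ".wav")
  for (i in seq_len(nrow(manifest))) {
    s <- corpus$samples[[manifest$sample_id[i]]]
    writeTextGrid(s, file.path(outDir, manifest$annotation_path[i]))
    if (audio) {
      aud <- synthesizeAudio(s, sampleRate = sampleRate,
                             seed = seed + i)
      writeWav(aud$wave, aud$sampleRate,
               file.path(outDir, manifest$audio_path[i]))
    }
  }
  writeCorpusTable(manifest, file.path(outDir, "manifest.csv"))
  invisible(manifest)
}

#' Segment a WAV file and report rhythm metrics
#'
#' @param wavPath path to a 16-bit PCM mono WAV file.
#' @param config a [SegmenterConfig-class].
#' @param minDurationS minimum reliable duration threshold (s).
#' @param outTextGrid optional path for the segmentation TextGrid.
#' @param outJson optional path for the metrics report JSON.
#' @return list with `sample` and `metrics` (see [segmentAudio()]).
#' @export
runSegment <- function(wavPath, config = segmenterConfig(),
                       minDurationS = 90, outTextGrid = NULL,
                       outJson = NULL) {
  aud <- readWav(wavPath)
  res <- segmentAudio(aud$wave, aud$sampleRate, config,
                      minDurationS = minDurationS,
                      sampleId = sub("\\.[^.]*$", "", basename(wavPath)))
  if (!is.null(outTextGrid)) writeTextGrid(res$sample, outTextGrid)
  if (!is.null(outJson))
    .writeReport(as.list(as.data.frame(res$metrics)), outJson)
  res
}

#' Plot a year-by-year metric series with period shading
#'
#' Requires ggplot2 (suggested dependency).
#'
#' @param series data.frame with columns `year`, `value`
#'   (see [metricSeries()]).
#' @param partition optional [PeriodPartition-class] whose breaks are drawn
#'   as vertical lines.
#' @param diagnosisYear optional reference year drawn as a dashed line.
#' @param ylab y-axis label.
#' @return a ggplot object.
#' @export
plotMetricSeries <- function(series, partition = NULL, diagnosisYear = NULL,
                             ylab = "%V") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    srStop("missingDependency", "plotMetricSeries requires ggplot2")
  year <- value <- NULL  # quiet R CMD check on aes() columns
  p <- ggplot2::ggplot(series, ggplot2::aes(x = year, y = value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "year", y = ylab) +
    ggplot2::theme_minimal()
  if (!is.null(partition))
    p <- p + ggplot2::geom_vline(xintercept = partition@breakYears - 0.5,
                                 linetype = "solid", colour = "grey40")
  if (!is.null(diagnosisYear))
    p <- p + ggplot2::geom_vline(xintercept = diagnosisYear,
                                 linetype = "dashed", colour = "red3")
  p
}
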