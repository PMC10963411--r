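# SpeechRhythm

Diachronic (longitudinal) analysis of speech rhythm from interval-labelled
recordings, aimed at tracking slow drifts and sudden shifts in a single
speaker's rhythm across years of archival audio — the setting that arises
when screening for the early rhythm changes of hypokinetic dysarthria, the
motor-speech disorder of Parkinson's disease.

The analysis rests on two rhythm indexes computed from a speech sample
segmented into vocalic (V), consonantal (C), disfluency (D) and silent-pause
(X) intervals:

- **%V** — the percentage of vocalic duration over phonation time:
  `%V = 100 * sum(V) / (sum(V) + sum(C))`. D and X intervals are excluded
  from both numerator and denominator.
- **VtoV** — the mean interval between two consecutive vowel onsets
  (the perceptual counterpart of articulation rate), in ms. Onset chains
  break at pauses and disfluencies, so excluded material never inflates the
  measure. The articulation rate follows as `AR = 1/VtoV` (syllables/s),
  displayed with one-decimal truncation.

Around these the package provides:

- **TextGrid I/O** (`readTextGrid`, `writeTextGrid`): Praat long and short
  text dialects, UTF-8/UTF-16, with strict V/C/D/X label validation and
  configurable handling of empty labels and tier gaps.
- **Minimum-duration (stabilization) analysis** (`stabilizationCurve`,
  `bandSummary`, `corpusBandSummary`): metrics over cumulative windows
  growing in 10 s steps, with band-wise SD summaries (10–40 s, 50–80 s,
  ≥ 90 s) and a recommended minimum sample duration.
- **Longitudinal changepoint analysis** (`findChangepoints`,
  `summarizePeriods`, `comparePeriods`): exact least-squares segmentation
  of a year-indexed metric series into periods, per-period summaries, and
  pairwise Welch (or pooled) t-tests.
- **A synthetic-data generator** (`generateSample`, `generateCorpus`,
  `synthesizeAudio`): gamma-duration V/C interval sequences calibrated to
  hit target %V and VtoV exactly in expectation, longitudinal corpora with
  a configurable %V staircase, and schematic audio (tone = V, noise = C,
  silence = X) with exact ground truth.
- **A prototype acoustic segmenter** (`segmentAudio`): labels audio into
  V/C/X from frame energy, periodicity and spectral flatness, then computes
  %V — a text-independent "90-second speech test" sketch, validated on
  synthetic audio only.

## Worked example

Generate a 43-year synthetic corpus (one 120 s sample per year, baseline
%V 45.3 stepping to 48.8 in 2010 and 50.3 in 2015, VtoV drifting
196 → 224 ms), compute metrics, and look for the changepoint:

```r
library(SpeechRhythm)

corpus <- generateCorpus(trajectoryParams(), seed = 1)
tab    <- metricsTable(corpus$samples)
head(tab[, c("sample_id", "year", "percent_v", "vtov_ms", "ar")], 3)
#>   sample_id year percent_v vtov_ms     ar
#> 1 y1979_s01 1979    44.528  194.37 5.1448
#> 2 y1980_s01 1980    46.790  194.51 5.1413
#> 3 y1981_s01 1981    44.703  195.36 5.1188

series <- metricSeries(tab, "percent_v")
part   <- findChangepoints(series, k = 2)
comparePeriods(series, part)
#> PeriodComparison (welch t-test, alpha = 0.05)
#>  period startYear endYear  n     mean        sd      min      max
#>       1      1979    2009 31 45.21951 0.8700448 43.82103 46.94938
#>       2      2010    2014  5 49.07488 1.1864159 47.12057 50.15777
#>       3      2015    2021  7 50.48850 0.2743549 50.17733 50.88589
#>  periodA periodB         t       df      pValue significant
#>        1       2 -6.970310 4.719278 0.001179595        TRUE
#>        2       3 -2.614802 4.307218 0.054890177       FALSE

part@breakYears[1] - 2015   # lead of the detected %V jump on diagnosis year
#> [1] -5
```

The recovered partition reproduces the generating staircase: a large,
highly significant %V step five years before the nominal diagnosis year,
followed by a smaller consolidation. Single samples can be inspected the
same way (`rhythmMetrics`), audited for minimum duration
(`runStabilize`), or segmented directly from audio (`runSegment`).

A command-line interface wrapping the same functions ships at
`inst/cli/speechrhythm.R` with subcommands `metrics`, `stabilize`,
`longitudinal`, `simulate` and `segment`.

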