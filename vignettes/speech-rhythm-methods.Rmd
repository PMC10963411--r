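---
title: "Rhythm metrics, stabilization and changepoint methods in SpeechRhythm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rhythm metrics, stabilization and changepoint methods in SpeechRhythm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpeechRhythm)
```

# The measurement model

SpeechRhythm analyses speech that has been segmented into an ordered,
non-overlapping sequence of intervals carrying one of four labels: vocalic
(V), consonantal (C), disfluency (D, e.g. false starts and vocalizations)
and silent pause (X). Two indexes summarize the rhythm of such a sample:

**%V** is the vocalic share of *phonation time*:

$$\%V = 100 \cdot \frac{\sum V}{\sum V + \sum C}.$$

D and X intervals contribute to neither numerator nor denominator. This is
a deliberate and load-bearing choice: pauses and disfluencies vary with
speech situation (interview vs monologue, audience vs none) far more than
articulation does, and including them would confound rhythm with fluency.
The denominator is therefore phonation time, not recording time.

**VtoV** is the mean interval between consecutive vowel onsets, in ms.
Vowel onsets approximate perceptual centres (P-centers), the moments
listeners perceive as the syllable beats, so VtoV is the perceptual
counterpart of articulation rate: $AR = 1/VtoV$, in syllables/s.

Two conventions in the VtoV computation deserve explanation:

- *Chain breaking.* How onset intervals interact with pauses is a genuine
  design choice; the package breaks the onset chain at every D or X
  interval (default `chainPolicy = "break"`). Concatenating across removed
  pauses would manufacture fictitiously short onset intervals; including
  pause time would inflate VtoV with non-articulatory material. A
  `"concatenate"` policy is provided for sensitivity analysis only.
- *Truncated display of AR.* Articulation rates are displayed by flooring
  to one decimal (`vtovToAR(..., "truncate")`): 1000/210 = 4.76 displays
  as 4.7, 1000/224 = 4.46 as 4.4. This is the one convention consistent
  with the three period values the package's acceptance checks reproduce
  (5.1, 4.7, 4.4 syllables/s from 196, 210, 224 ms); full precision is
  always retained internally.

Undefined metrics (zero phonation time, fewer than two chained onsets) are
classed errors, never silent zeros or NaNs, so downstream tables cannot
absorb fabricated values.

# Minimum sample duration: the stabilization procedure

Short excerpts give unreliable rhythm estimates: a run of vowels or a
cluster-heavy phrase can swing %V by several points. To find the minimum
duration at which estimates settle, `stabilizationCurve()` computes both
metrics on cumulative prefixes of the recording — 10 s, 20 s, 30 s, … —
and `bandSummary()` reports the SD of the curve within three window bands:
10–40 s, 50–80 s, and ≥ 90 s. Points at 40–50 s and 80–90 s belong to no
band; the bands are used as given rather than re-derived. The recommended
minimum duration is the lower edge of the first band whose %V SD drops
below 0.5 percentage points — a threshold chosen to separate the
several-point swings of short windows from the sub-half-point flutter of
stabilized ones. The below-minimum-duration flag in `rhythmMetrics()`
defaults to 90 s, the lower edge of the last band, as the conservative
choice for unseen material.

Numerical conventions here:

- Window length counts *recording* time, pauses included — the windows are
  stretches of recording, and a minimum-duration recommendation must be
  phrased in recording time to be actionable.
- The interval straddling a window boundary is split and its left part
  kept (`partialInterval = "split"`), so every window is exactly its
  nominal length; `"drop"` is available.
- SDs use the sample (n−1) convention throughout, switchable to
  population (`sdType`). The package does not mix conventions.
- `corpusBandSummary()` aggregates as the arithmetic mean of per-sample
  band SDs — a mean of SDs, not an SD of pooled points.

# Longitudinal changepoint analysis

A year-indexed series of per-sample %V (or VtoV) values is segmented into
periods by `findChangepoints()`: exhaustive search over placements of *k*
break years minimizing the within-period sum of squared deviations from
period means. Exhaustive search is the transparent choice at this scale
(tens of observations, hundreds of candidate placements) and is verified
in the tests against an independent recursive enumeration. Ties are broken
toward the earliest break years, which makes the degenerate constant-series
case deterministic. The default *k* = 2 yields three periods, matching the
baseline / transition / post-change structure the package is designed to
detect; *k* is a parameter, not an inference — the package deliberately
offers no automatic model selection for *k*.

`comparePeriods()` then runs two-sample t-tests between adjacent periods
(optionally all pairs). Welch's unequal-variance test is the default
because the periods of interest typically have very different spreads
(e.g. a tight post-change plateau after a variable baseline); the pooled
test is available. p-values are reported per comparison without
multiplicity correction — with two or three planned adjacent contrasts the
raw per-comparison p is the quantity of interest; users needing family-wise
control can apply `p.adjust` to the reported column.

The diagnosis year is *metadata*: it annotates reports
(`breakYear - diagnosisYear`, negative = lead) and is never inferred from
the data.

# The synthetic-data generator

`generateSample()` produces strictly alternating V/C sequences with
gamma-distributed durations. Given targets $p$ (%V/100) and $m$ (VtoV, s),
durations have means $E[V] = pm$ and $E[C] = (1-p)m$, so without pauses
the expected vocalic share and the expected onset interval both hit their
targets exactly — the calibration identity the recovery tests assert at
600 s. Choices and what they mean:

- *Gamma, CV 0.4.* Positive support and a closed-form mean/CV mapping;
  a CV of 0.4 approximates the variability of natural segment durations.
  `durationCv = 0` degenerates to exact deterministic durations.
- *Pauses and disfluencies* are Poisson processes over phonation time
  (defaults 0.05/s and 0.01/s), inserted at C→V boundaries; pause
  durations have a 0.25 s floor (the conventional silent-pause minimum)
  with an exponential tail to a 0.8 s mean.
- *Strict V/C alternation* is a simplification — real speech has consonant
  clusters and vowel hiatus — but it preserves exactly the two quantities
  the analysis measures, which is the fidelity that matters here.

`generateCorpus()` draws per-sample target %V from a piecewise-constant
staircase over periods (defaults: means 45.3/48.8/50.3, SDs
0.87/0.85/0.37, breaks at 2010 and 2015 over years 1979–2021, one 120 s
sample per year) and drifts target VtoV linearly from 196 to 224 ms; the
linear form is the minimal assumption for a trend described only as a
general increase. The per-year sample count and per-sample duration are
plausible defaults for an archival-interview corpus, not facts about any
particular corpus.

What passing tests on this generator do and do not show: they validate the
*pipeline* — metric arithmetic, stabilization ordering, changepoint
recovery at realistic effect sizes — under a model whose assumptions
(independent gamma durations, stationarity within a sample, a clean
staircase across years) real speech only approximates. They do not
validate segmentation of natural audio, speaker idiosyncrasy, or style
confounds.

# Schematic audio and the acoustic segmenter

`synthesizeAudio()` renders V as a pulse train at 120 Hz shaped by two
fixed resonators (≈500 and 1500 Hz — a schematic vowel with a formant-like
spectrum), C as white noise 10 dB below the vocalic RMS (20% of C
intervals silent, mimicking stop closures), X/D as silence, with 5 ms
raised-cosine ramps. It is deliberately not a speech synthesizer: its sole
purpose is audio whose V/C/X ground truth is known exactly.

`segmentAudio()` is a prototype of a text-independent rhythm "speech
test": no recognition, no forced alignment, only acoustics. Per 25 ms
frame (10 ms hop) it computes RMS energy, the normalized autocorrelation
peak in the 60–400 Hz pitch range (computed unwindowed with unbiased lag
scaling, so a periodic frame scores near 1), and spectral flatness. Frames
are labelled X below the silence threshold (the larger of −60 dBFS and
noise floor + 10 dB), V when periodic (≥ 0.45) and spectrally peaked
(flatness ≤ 0.3), else C, then majority-smoothed over 5 frames. Runs
become intervals; intervals under 20 ms are absorbed into the longer
neighbour, and silences shorter than 250 ms are relabelled C — the
phonetics convention that sub-threshold gaps are stop closures, not
pauses, which is also what lets the silent-C renderings be recovered as
consonants.

On synthetic audio the prototype recovers %V within about 2 points
(tested at ±3), places over 90% of boundaries within 20 ms, is monotone
across %V targets 40–55, and is invariant to ±6 dB gain. All thresholds
are engineering choices validated only in this tone/noise world; natural
speech blurs the V/C boundary at approximants and nasals, and no accuracy
claim is made there.

# Problem sizes and degenerate inputs

The test suite and acceptance checks run at deliberately chosen scales:
600 s samples for generator calibration, 300 s × 100 seeds for the
stabilization ordering, 43-year corpora × 100 seeds for changepoint
recovery, and 120 s utterances for the audio round trip — sizes at which
the asserted tolerances follow from the law of large numbers with margin,
while the whole suite stays quick to run.

Degenerate inputs are handled explicitly: zero-phonation samples and
single-onset chains raise classed undefined-metric errors; samples shorter
than one stabilization step raise an empty-curve error; periods with one
observation report NA SD; constant series return the earliest feasible
break with zero improvement; empty TextGrid tiers round-trip as empty
samples.

# Known limitations

- The V/C/D/X annotation is taken as given; the package performs no
  diarization and assumes interviewer speech and audience noise are absent
  from the annotated tier.
- Only %V and VtoV are implemented; other typology metrics (ΔV, ΔC, nPVI,
  varco) are out of scope.
- The changepoint model is piecewise-constant with fixed *k*; no trend
  models, no online detection, no automatic *k* selection.
- The acoustic segmenter is a synthetic-world prototype, not a clinical
  instrument; nothing in this package constitutes a diagnostic claim.
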