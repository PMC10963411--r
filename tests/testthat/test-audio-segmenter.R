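sr <- 16000

test_that("schematic audio has the expected per-interval energy structure", {
  oneV <- synthesizeAudio(sampleFromDurations(0.5, "V"), seed = 1)
  w <- oneV$wave
  inside <- w[round(0.05 * sr):round(0.45 * sr)]
  expect_gt(sqrt(mean(inside^2)), 0.05)

  vcx <- sampleFromDurations(c(0.5, 0.5, 0.5), c("V", "C", "X"))
  aud <- synthesizeAudio(vcx, cSnrDb = 10, silentCFraction = 0, seed = 2)
  seg <- function(a, b) aud$wave[round(a * sr):round(b * sr)]
  rmsV <- sqrt(mean(seg(0.05, 0.45)^2))
  rmsC <- sqrt(mean(seg(0.55, 0.95)^2))
  rmsX <- sqrt(mean(seg(1.05, 1.45)^2))
  expect_equal(20 * log10(rmsV / rmsC), 10, tolerance = 1)
  expect_equal(rmsX, 0)

  allX <- synthesizeAudio(sampleFromDurations(c(1, 1), c("X", "D")), seed = 3)
  expect_true(all(allX$wave == 0))

  expect_error(synthesizeAudio(new("SpeechSample")),
               class = "SpeechRhythm_emptyInput")
})

test_that("audio synthesis and WAV I/O round trip deterministically", {
  s <- generateSample(generatorConfig(durationS = 3, seed = 5))
  a <- synthesizeAudio(s, seed = 4)
  b <- synthesizeAudio(s, seed = 4)
  expect_identical(a$wave, b$wave)

  f <- tempfile(fileext = ".wav")
  writeWav(a$wave, a$sampleRate, f)
  back <- readWav(f)
  expect_equal(back$sampleRate, sr)
  expect_equal(length(back$wave), length(a$wave))
  expect_lt(max(abs(back$wave - a$wave)), 1 / 32767 + 1e-9)  # 16-bit quantization
})

test_that("features separate tone, noise and silence as designed", {
  tone <- synthesizeAudio(sampleFromDurations(1, "V"), seed = 1)$wave
  fTone <- extractFeatures(tone, sr)
  interior <- seq(10, length(fTone@times) - 10)
  expect_gt(median(fTone@periodicity[interior]), 0.8)
  expect_lt(median(fTone@flatness[interior]), 0.2)

  set.seed(99)
  noise <- rnorm(sr) * 0.03
  fNoise <- extractFeatures(noise, sr)
  expect_lt(median(fNoise@periodicity), 0.3)
  expect_gt(median(fNoise@flatness), 0.5)

  silence <- numeric(sr)
  fSil <- extractFeatures(silence, sr)
  expect_true(all(fSil@energyDb < -150))

  expect_error(extractFeatures(numeric(0), sr),
               class = "SpeechRhythm_emptyInput")
  expect_error(extractFeatures(noise, 4000), class = "SpeechRhythm_badInput")
})

test_that("frame classification applies thresholds then median smoothing", {
  mkFeat <- function(e, per, flat) {
    n <- length(e)
    new("FrameFeatures", times = (seq_len(n) - 1) * 0.01 + 0.0125,
        energyDb = e, periodicity = per, flatness = flat,
        sampleRate = sr, frameS = 0.025, hopS = 0.01)
  }
  # all silent
  f <- mkFeat(rep(-100, 20), rep(0, 20), rep(0.5, 20))
  expect_true(all(classifyFrames(f) == "X"))

  # tone block then noise block
  f <- mkFeat(rep(-20, 40), c(rep(0.9, 20), rep(0.1, 20)),
              c(rep(0.05, 20), rep(0.7, 20)))
  lab <- classifyFrames(f)
  expect_true(all(lab[1:20] == "V"))
  expect_true(all(lab[21:40] == "C"))

  # a single deviant frame inside a V run is absorbed by the majority filter
  per <- rep(0.9, 30); per[15] <- 0.1
  flat <- rep(0.05, 30); flat[15] <- 0.7
  f <- mkFeat(rep(-20, 30), per, flat)
  expect_true(all(classifyFrames(f) == "V"))
})

test_that("frame runs merge into intervals with closure and minimum-length rules", {
  cfg <- segmenterConfig()
  mkFeat <- function(n) {
    new("FrameFeatures", times = (seq_len(n) - 1) * 0.01 + 0.0125,
        energyDb = rep(-20, n), periodicity = rep(0.5, n),
        flatness = rep(0.2, n), sampleRate = sr, frameS = 0.025,
        hopS = 0.01)
  }
  # 10 V frames at 10 ms hop become a single interval of about 0.1 s
  s <- framesToIntervals(rep("V", 10), mkFeat(10), cfg)
  expect_equal(nrow(intervals(s)), 1L)
  expect_equal(intervals(s)$label, "V")
  expect_lt(abs(intervals(s)$end - intervals(s)$start - 0.1), 0.03)

  # an X gap of 0.1 s between V runs is below the pause floor: relabelled C
  lab <- c(rep("V", 20), rep("X", 10), rep("V", 20))
  s <- framesToIntervals(lab, mkFeat(50), cfg)
  expect_equal(intervals(s)$label, c("V", "C", "V"))

  # an X gap of 0.4 s survives as a pause
  lab <- c(rep("V", 20), rep("X", 40), rep("V", 20))
  s <- framesToIntervals(lab, mkFeat(80), cfg)
  expect_equal(intervals(s)$label, c("V", "X", "V"))
})

test_that("segmentation boundaries track ground truth on clean synthetic audio", {
  g <- generateSample(generatorConfig(targetPercentV = 45, targetVtovMs = 200,
                                      durationS = 30, durationCv = 0.3,
                                      seed = 5))
  aud <- synthesizeAudio(g, seed = 9)
  res <- segmentAudio(aud$wave, aud$sampleRate)
  ivp <- intervals(g)
  ivp <- ivp[ivp$label %in% c("V", "C"), ]
  truthEdges <- sort(unique(c(ivp$start, ivp$end)))
  estEdges <- sort(unique(unlist(intervals(res$sample)[, c("start", "end")])))
  nearest <- vapply(truthEdges, function(t) min(abs(estEdges - t)), 0)
  expect_gte(mean(nearest <= 0.02), 0.9)
})

test_that("estimated %V recovers ground truth and is monotone across targets", {
  est <- truth <- numeric(0)
  for (tv in c(40, 45, 50, 55)) {
    g <- generateSample(generatorConfig(targetPercentV = tv,
                                        targetVtovMs = 200,
                                        durationS = 60, seed = 3))
    aud <- synthesizeAudio(g, seed = 11)
    res <- segmentAudio(aud$wave, aud$sampleRate)
    est <- c(est, res$metrics@percentV)
    truth <- c(truth, percentV(g))
  }
  expect_true(all(abs(est - truth) <= 3))
  expect_true(all(diff(est) > 0))
})

test_that("segmentation is amplitude-invariant within +/- 6 dB and deterministic", {
  g <- generateSample(generatorConfig(durationS = 20, seed = 6))
  aud <- synthesizeAudio(g, seed = 2)
  base <- segmentAudio(aud$wave, aud$sampleRate)
  again <- segmentAudio(aud$wave, aud$sampleRate)
  expect_identical(intervals(base$sample), intervals(again$sample))
  for (gainDb in c(-6, 6)) {
    scaled <- aud$wave * 10^(gainDb / 20)
    res <- segmentAudio(scaled, aud$sampleRate)
    expect_equal(intervals(res$sample), intervals(base$sample),
                 tolerance = 1e-9)
  }
})

test_that("a silent recording yields an undefined-metric error", {
  expect_error(segmentAudio(numeric(sr * 2), sr),
               class = "SpeechRhythm_undefinedMetric")
})
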