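test_that("identical seeds give bit-identical samples; different seeds differ", {
  a <- generateSample(generatorConfig(seed = 7))
  b <- generateSample(generatorConfig(seed = 7))
  expect_identical(intervals(a), intervals(b))
  c_ <- generateSample(generatorConfig(seed = 8))
  expect_false(identical(intervals(a), intervals(c_)))
})

test_that("zero duration CV degenerates to exact deterministic durations", {
  s <- generateSample(generatorConfig(targetPercentV = 50,
                                      targetVtovMs = 200, durationS = 10,
                                      durationCv = 0, pauseRatePerS = 0,
                                      disfluencyRatePerS = 0, seed = 1))
  iv <- intervals(s)
  expect_true(all(abs(iv$end - iv$start - 0.1) < 1e-12))
  expect_equal(percentV(s), 50, tolerance = 1e-9)
  expect_equal(vtov(s)$vtovMs, 200, tolerance = 1e-9)
})

test_that("generated samples recover their calibration targets without pauses", {
  for (seed in 1:5) {
    s <- generateSample(generatorConfig(targetPercentV = 50,
                                        targetVtovMs = 200,
                                        durationS = 600,
                                        pauseRatePerS = 0,
                                        disfluencyRatePerS = 0,
                                        seed = seed))
    expect_lt(abs(percentV(s) - 50), 1.0)
    expect_lt(abs(vtov(s)$vtovMs - 200), 4)
  }
})

test_that("default configuration reproduces the baseline-period calibration", {
  s <- generateSample(generatorConfig(durationS = 300, seed = 13))
  m <- rhythmMetrics(s)
  expect_lt(abs(m@percentV - 45.3), 1.5)
  expect_lt(abs(m@vtovMs - 196), 6)
})

test_that("inserting pauses leaves %V essentially unchanged on seeded pairs", {
  diffs <- vapply(1:10, function(seed) {
    noP <- generateSample(generatorConfig(durationS = 200, pauseRatePerS = 0,
                                          disfluencyRatePerS = 0,
                                          seed = seed))
    withP <- generateSample(generatorConfig(durationS = 200,
                                            pauseRatePerS = 0.08,
                                            disfluencyRatePerS = 0.02,
                                            seed = seed))
    percentV(withP) - percentV(noP)
  }, 0)
  expect_lt(max(abs(diffs)), 1.0)
  expect_lt(abs(mean(diffs)), 0.5)
})

test_that("generated pauses respect the 250 ms floor and alternation is strict V/C", {
  s <- generateSample(generatorConfig(durationS = 300, pauseRatePerS = 0.2,
                                      seed = 3))
  iv <- intervals(s)
  xDur <- (iv$end - iv$start)[iv$label == "X"]
  expect_gt(length(xDur), 0)
  expect_true(all(xDur >= 0.25 - 1e-9))
  # every V is followed by a C (except possibly the trimmed tail)
  vPos <- which(iv$label == "V")
  vPos <- vPos[vPos < nrow(iv)]
  expect_true(all(iv$label[vPos + 1L] == "C"))
})

test_that("infeasible generator configurations are rejected", {
  expect_error(generatorConfig(pauseMeanS = 0.1))
  expect_error(generatorConfig(targetPercentV = 0))
  expect_error(generatorConfig(targetVtovMs = -5))
  expect_error(generatorConfig(durationS = 0))
})

test_that("longitudinal corpus has years x samplesPerYear entries with the configured staircase", {
  params <- trajectoryParams(years = 1979:2021, samplesPerYear = 1L,
                             sampleDurationS = 15)
  corpus <- generateCorpus(params, seed = 5)
  expect_equal(nrow(corpus$manifest), 43L)
  expect_equal(length(corpus$samples), 43L)

  tw <- trajectoryParams(years = 2001:2010, samplesPerYear = 3L,
                         breakYears = 2006,
                         periodMeansPercentV = c(45, 50),
                         periodSdsPercentV = c(0.9, 0.4),
                         sampleDurationS = 15)
  corpus3 <- generateCorpus(tw, seed = 5)
  expect_equal(nrow(corpus3$manifest), 30L)

  # target staircase: post-break targets sit clearly above pre-break ones
  m <- corpus3$manifest
  expect_gt(mean(m$target_percent_v[m$year >= 2006]),
            mean(m$target_percent_v[m$year < 2006]) + 3)
  # VtoV drift is linear between the endpoints
  expect_equal(m$target_vtov_ms[m$year == 2001][1], 196)
  expect_equal(m$target_vtov_ms[m$year == 2010][1], 224)
})

test_that("corpus generation is reproducible under a fixed seed", {
  p <- trajectoryParams(years = 2001:2005, breakYears = 2003,
                        periodMeansPercentV = c(45.3, 48.8),
                        periodSdsPercentV = c(0.87, 0.85),
                        sampleDurationS = 15)
  a <- generateCorpus(p, seed = 9)
  b <- generateCorpus(p, seed = 9)
  expect_identical(a$manifest$target_percent_v, b$manifest$target_percent_v)
  expect_identical(intervals(a$samples[[3]]), intervals(b$samples[[3]]))
})

test_that("a flat trajectory yields mostly non-significant period contrasts", {
  params <- trajectoryParams(years = 1996:2020,
                             periodMeansPercentV = c(45.3, 45.3, 45.3),
                             periodSdsPercentV = c(0.87, 0.87, 0.87),
                             breakYears = c(2010, 2015),
                             sampleDurationS = 60)
  fixedPartition <- new("PeriodPartition", breakYears = c(2010, 2015),
                        periods = data.frame(startYear = c(1996, 2010, 2015),
                                             endYear = c(2009, 2014, 2020)),
                        rss = NA_real_, improvement = NA_real_)
  hits <- 0L
  nSeeds <- 60
  for (seed in seq_len(nSeeds)) {
    corpus <- generateCorpus(params, seed = 2000 + seed)
    tab <- metricsTable(corpus$samples, minDurationS = 90)
    series <- metricSeries(tab)
    cmp <- comparePeriods(series, fixedPartition)
    if (cmp@tests$pValue[1] < 0.05) hits <- hits + 1L
  }
  # null comparison at alpha 0.05: ~5% expected; allow generous slack
  expect_lte(hits, ceiling(0.12 * nSeeds))
})

test_that("trajectory validity catches inconsistent period parameters", {
  expect_error(trajectoryParams(periodMeansPercentV = c(45, 50)))  # 2 means, 2 breaks
  expect_error(trajectoryParams(breakYears = c(1950),
                                periodMeansPercentV = c(45, 50),
                                periodSdsPercentV = c(1, 1)))
  expect_error(trajectoryParams(periodSdsPercentV = c(0.9, 0, 0.4)))
})
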