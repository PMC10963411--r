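test_that("long-format TextGrid is parsed and cross-checked against an independent text parse", {
  f <- writeFixture(longTextGridFixture())
  s <- readTextGrid(f, "segments")
  iv <- intervals(s)
  expect_equal(nrow(iv), 3L)
  expect_equal(iv$label, c("V", "C", "V"))
  expect_equal(phonationTime(s), 0.30, tolerance = 1e-9)

  # independent parse: pull xmin/xmax/text with a flat regex scan
  lines <- readLines(f)
  xs <- as.numeric(sub(".*= ", "", grep("xmin =", lines, value = TRUE)[-(1:2)]))
  xe <- as.numeric(sub(".*= ", "", grep("xmax =", lines, value = TRUE)[-(1:2)]))
  tx <- sub('.*text = "(.*)".*', "\\1", grep("text =", lines, value = TRUE))
  expect_equal(iv$start, xs, tolerance = 1e-9)
  expect_equal(iv$end, xe, tolerance = 1e-9)
  expect_equal(iv$label, tx)
})

test_that("short and long dialects of the same annotation give identical samples", {
  sLong <- readTextGrid(writeFixture(longTextGridFixture()), "segments")
  sShort <- readTextGrid(writeFixture(shortTextGridFixture()), "segments")
  expect_equal(intervals(sLong)$start, intervals(sShort)$start, tolerance = 1e-9)
  expect_equal(intervals(sLong)$end, intervals(sShort)$end, tolerance = 1e-9)
  expect_equal(intervals(sLong)$label, intervals(sShort)$label)
})

test_that("write/read round trip preserves labels and times for random samples", {
  for (seed in 1:5) {
    s <- randomSample(40, seed = seed)
    f <- tempfile(fileext = ".TextGrid")
    writeTextGrid(s, f)
    s2 <- readTextGrid(f, "segments")
    expect_equal(intervals(s2)$label, intervals(s)$label)
    expect_equal(intervals(s2)$start, intervals(s)$start, tolerance = 1e-6)
    expect_equal(intervals(s2)$end, intervals(s)$end, tolerance = 1e-6)
  }
  # D and X survive a round trip verbatim
  s <- sampleFromDurations(c(0.2, 0.3, 0.4, 0.25), c("V", "D", "C", "X"))
  f <- tempfile(fileext = ".TextGrid")
  writeTextGrid(s, f)
  expect_equal(intervals(readTextGrid(f))$label, c("V", "D", "C", "X"))
})

test_that("an empty sample writes a valid TextGrid with one empty tier", {
  s <- new("SpeechSample")
  f <- tempfile(fileext = ".TextGrid")
  writeTextGrid(s, f)
  s2 <- readTextGrid(f, "segments")
  expect_equal(nrow(intervals(s2)), 0L)
})

test_that("label handling: normalization is idempotent, unknown labels error, empty labels follow policy", {
  s <- speechSample(c(0, 0.1), c(0.1, 0.2), c(" v ", "C"))
  expect_equal(intervals(s)$label, c("V", "C"))
  # idempotent: normalizing an already-normalized sample changes nothing
  s2 <- speechSample(intervals(s)$start, intervals(s)$end, intervals(s)$label)
  expect_identical(intervals(s2)$label, intervals(s)$label)

  expect_error(speechSample(0, 0.1, "s"), class = "SpeechRhythm_labellingError")

  fx <- longTextGridFixture()
  fx[grep('text = "C"', fx)] <- '            text = "s" '
  expect_error(readTextGrid(writeFixture(fx), "segments"),
               class = "SpeechRhythm_labellingError")

  fx <- longTextGridFixture()
  fx[grep('text = "C"', fx)] <- '            text = "" '
  sX <- readTextGrid(writeFixture(fx), "segments")
  expect_equal(intervals(sX)$label, c("V", "X", "V"))
  expect_error(readTextGrid(writeFixture(fx), "segments", emptyLabel = "error"),
               class = "SpeechRhythm_labellingError")
})

test_that("missing tier, point tier and gaps are handled per policy", {
  f <- writeFixture(longTextGridFixture())
  expect_error(readTextGrid(f, "nope"), class = "SpeechRhythm_missingTier")

  fx <- longTextGridFixture()
  fx[grep("IntervalTier", fx)] <- '        class = "TextTier" '
  expect_error(readTextGrid(writeFixture(fx), "segments"),
               class = "SpeechRhythm_tierType")

  # a gap in the tier becomes an X interval by default
  fx <- longTextGridFixture()
  fx[grep("xmin = 0.20", fx)] <- '            xmin = 0.22 '
  sG <- readTextGrid(writeFixture(fx), "segments")
  expect_equal(intervals(sG)$label, c("V", "C", "X", "V"))
  expect_equal(intervals(sG)$start[3], 0.20, tolerance = 1e-9)
  expect_equal(intervals(sG)$end[3], 0.22, tolerance = 1e-9)
  expect_error(readTextGrid(writeFixture(fx), "segments", gapPolicy = "error"),
               class = "SpeechRhythm_parseError")
})

test_that("UTF-16 TextGrids are read identically to UTF-8", {
  f8 <- writeFixture(longTextGridFixture())
  f16 <- tempfile(fileext = ".TextGrid")
  con <- file(f16, open = "w", encoding = "UTF-16LE")
  writeLines(longTextGridFixture(), con)
  close(con)
  a <- readTextGrid(f8, "segments")
  b <- readTextGrid(f16, "segments")
  expect_equal(intervals(a), intervals(b), tolerance = 1e-9)
})

test_that("corpus manifest is validated and sorted by year then id", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,year,annotation_path",
               "b,2021,b.TextGrid",
               "a,1979,a.TextGrid"), f)
  tab <- readCorpusTable(f)
  expect_equal(tab$sample_id, c("a", "b"))
  expect_equal(tab$year, c(1979L, 2021L))

  writeLines(c("sample_id,year,annotation_path",
               "a,1979,a.TextGrid",
               "a,2000,b.TextGrid"), f)
  expect_error(readCorpusTable(f), class = "SpeechRhythm_duplicateId")

  writeLines(c("sample_id,year,annotation_path",
               "a,nineteen,a.TextGrid"), f)
  expect_error(readCorpusTable(f), class = "SpeechRhythm_parseError")
})

test_that("a generated manifest round-trips through the corpus table reader", {
  corpus <- generateCorpus(trajectoryParams(years = 2001:2020,
                                            sampleDurationS = 20), seed = 3)
  f <- tempfile(fileext = ".csv")
  writeCorpusTable(corpus$manifest, f)
  tab <- readCorpusTable(f)
  expect_equal(nrow(tab), 20L)
  expect_equal(sort(tab$sample_id), sort(corpus$manifest$sample_id))
})

test_that("SpeechSample validity rejects malformed interval sets", {
  expect_error(speechSample(0.1, 0.1, "V"))            # zero duration
  expect_error(speechSample(c(0, 0.05), c(0.1, 0.15), c("V", "C"))) # overlap
  expect_error(speechSample(c(0.2, 0), c(0.3, 0.1), c("V", "C")))   # unsorted
})
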