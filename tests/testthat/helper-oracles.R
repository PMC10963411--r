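# Independent brute-force oracles and fixture builders. These deliberately
# use plain loops and closed-form statistics so they share no code with the
# implementation they check.

# %V by direct loop over intervals.
oraclePercentV <- function(iv) {
  v <- 0; cc <- 0
  for (i in seq_len(nrow(iv))) {
    d <- iv$end[i] - iv$start[i]
    if (iv$label[i] == "V") v <- v + d
    if (iv$label[i] == "C") cc <- cc + d
  }
  100 * v / (v + cc)
}

# VtoV by direct loop: D or X resets the onset chain; C does not.
oracleVtoV <- function(iv) {
  diffs <- numeric(0)
  lastOnset <- NA_real_
  for (i in seq_len(nrow(iv))) {
    lab <- iv$label[i]
    if (lab %in% c("D", "X")) {
      lastOnset <- NA_real_
    } else if (lab == "V") {
      if (!is.na(lastOnset)) diffs <- c(diffs, iv$start[i] - lastOnset)
      lastOnset <- iv$start[i]
    }
  }
  list(vtovMs = if (length(diffs)) mean(diffs) * 1000 else NA_real_,
       n = length(diffs))
}

# Closed-form Welch two-sample t-test.
oracleWelch <- function(x, y) {
  vx <- var(x); vy <- var(y); nx <- length(x); ny <- length(y)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

# Exhaustive changepoint search by explicit recursion over break-year
# placements, with segment RSS computed by plain loops.
oracleChangepoints <- function(year, value, k) {
  years <- sort(unique(year))
  segRss <- function(sel) {
    v <- value[sel]
    m <- sum(v) / length(v)
    s <- 0
    for (vi in v) s <- s + (vi - m)^2
    s
  }
  best <- list(rss = Inf, breaks = NULL)
  recurse <- function(chosen, candidates) {
    if (length(chosen) == k) {
      edges <- c(-Inf, chosen, Inf)
      r <- 0
      for (s in seq_len(k + 1)) {
        sel <- year >= edges[s] & year < edges[s + 1]
        if (!any(sel)) return(invisible(NULL))
        r <- r + segRss(sel)
      }
      if (r < best$rss - 1e-12) best <<- list(rss = r, breaks = chosen)
      return(invisible(NULL))
    }
    for (i in seq_along(candidates))
      recurse(c(chosen, candidates[i]),
              candidates[-seq_len(i)])
  }
  recurse(numeric(0), years[-1])
  best
}

# Random labelled sample for property tests: mixed V/C/D/X, random
# durations, contiguous timeline.
randomSample <- function(n = 50, seed = 1) {
  set.seed(seed)
  labels <- sample(c("V", "C", "D", "X"), n, replace = TRUE,
                   prob = c(0.4, 0.4, 0.05, 0.15))
  # guarantee a usable VtoV: open with an uninterrupted V C V run
  labels[1:3] <- c("V", "C", "V")
  durations <- runif(n, 0.03, 0.6)
  sampleFromDurations(durations, labels,
                      sampleId = sprintf("rand%d", seed))
}

# Hand-built long-format TextGrid fixture: V[0,0.12] C[0.12,0.20] V[0.20,0.30].
longTextGridFixture <- function() {
  c('File type = "ooTextFile"',
    'Object class = "TextGrid"',
    '',
    'xmin = 0 ',
    'xmax = 0.3 ',
    'tiers? <exists> ',
    'size = 1 ',
    'item []: ',
    '    item [1]:',
    '        class = "IntervalTier" ',
    '        name = "segments" ',
    '        xmin = 0 ',
    '        xmax = 0.3 ',
    '        intervals: size = 3 ',
    '        intervals [1]:',
    '            xmin = 0 ',
    '            xmax = 0.12 ',
    '            text = "V" ',
    '        intervals [2]:',
    '            xmin = 0.12 ',
    '            xmax = 0.20 ',
    '            text = "C" ',
    '        intervals [3]:',
    '            xmin = 0.20 ',
    '            xmax = 0.30 ',
    '            text = "V" ')
}

# The same annotation in the short dialect.
shortTextGridFixture <- function() {
  c('File type = "ooTextFile"',
    'Object class = "TextGrid"',
    '',
    '0',
    '0.3',
    '<exists>',
    '1',
    '"IntervalTier"',
    '"segments"',
    '0',
    '0.3',
    '3',
    '0',
    '0.12',
    '"V"',
    '0.12',
    '0.20',
    '"C"',
    '0.20',
    '0.30',
    '"V"')
}

writeFixture <- function(lines) {
  f <- tempfile(fileext = ".TextGrid")
  writeLines(lines, f)
  f
}
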