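# Praat TextGrid reading/writing and corpus manifest handling.
#
# Both TextGrid text dialects are supported: the verbose "long" format
# (xmin = 0) and the "short" format (bare values, quoted strings). Praat
# writes UTF-8 or UTF-16 with a byte-order mark; both are handled.

# Read all lines of a (possibly UTF-16) Praat text file.
.readPraatLines <- function(path) {
  bytes <- readBin(path, "raw", n = 4L)
  enc <- if (length(bytes) >= 2L && bytes[1L] == as.raw(0xFF) &&
             bytes[2L] == as.raw(0xFE)) "UTF-16LE"
         else if (length(bytes) >= 2L && bytes[1L] == as.raw(0xFE) &&
                  bytes[2L] == as.raw(0xFF)) "UTF-16BE"
         # BOM-less UTF-16: ASCII text shows interleaved NUL bytes
         else if (length(bytes) >= 2L && bytes[2L] == as.raw(0)) "UTF-16LE"
         else if (length(bytes) >= 2L && bytes[1L] == as.raw(0)) "UTF-16BE"
         else "UTF-8"
  con <- file(path, encoding = enc)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  # strip a UTF-8 BOM if present
  if (length(lines) && nchar(lines[1L]))
    lines[1L] <- sub("^﻿", "", lines[1L])
  lines
}

# Praat string literals escape embedded quotes by doubling them.
.unquotePraat <- function(x) gsub("\"\"", "\"", x, fixed = TRUE)

# Parse a long-dialect TextGrid into a list of tiers.
.parseLongTextGrid <- function(lines) {
  numAfter <- function(pat, x) as.numeric(sub(pat, "\\1", x))
  strAfter <- function(pat, x) .unquotePraat(sub(pat, "\\1", x))
  tiers <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- lines[i]
    if (grepl("^\\s*class\\s*=\\s*\"", ln)) {
      cls <- strAfter(".*class\\s*=\\s*\"(.*)\"\\s*$", ln)
      nm <- NA_character_
      j <- i + 1L
      while (j <= n && !grepl("name\\s*=\\s*\"", lines[j])) j <- j + 1L
      if (j <= n) nm <- strAfter(".*name\\s*=\\s*\"(.*)\"\\s*$", lines[j])
      tier <- list(class = cls, name = nm,
                   xmin = numeric(0), xmax = numeric(0), text = character(0))
      # walk entries until the next tier (or EOF)
      j <- j + 1L
      curr <- NULL
      while (j <= n && !grepl("^\\s*class\\s*=\\s*\"", lines[j])) {
        lj <- lines[j]
        if (grepl("^\\s*(intervals|points)\\s*\\[", lj)) {
          curr <- list()
        } else if (grepl("xmin\\s*=", lj) && !is.null(curr)) {
          curr$xmin <- numAfter(".*xmin\\s*=\\s*([-0-9.eE+]+).*", lj)
        } else if (grepl("xmax\\s*=", lj) && !is.null(curr)) {
          curr$xmax <- numAfter(".*xmax\\s*=\\s*([-0-9.eE+]+).*", lj)
        } else if (grepl("(number|time)\\s*=", lj) && !is.null(curr)) {
          curr$xmin <- numAfter(".*(?:number|time)\\s*=\\s*([-0-9.eE+]+).*", lj)
          curr$xmax <- curr$xmin
        } else if (grepl("(text|mark)\\s*=\\s*\"", lj) && !is.null(curr)) {
          txt <- strAfter(".*(?:text|mark)\\s*=\\s*\"(.*)\"\\s*$", lj)
          tier$xmin <- c(tier$xmin, curr$xmin)
          tier$xmax <- c(tier$xmax, curr$xmax)
          tier$text <- c(tier$text, txt)
          curr <- NULL
        }
        j <- j + 1L
      }
      tiers[[length(tiers) + 1L]] <- tier
      i <- j
    } else {
      i <- i + 1L
    }
  }
  tiers
}

# Parse a short-dialect TextGrid: after the 2 header lines and blank line,
# tokens appear one per line: xmin, xmax, <exists>, ntiers, then per tier
# class, name, xmin, xmax, n, then per interval xmin, xmax, text.
.parseShortTextGrid <- function(lines) {
  toks <- lines[nzchar(trimws(lines))]
  toks <- toks[-(1:2)]                       # File type / Object class
  isStr <- function(x) grepl("^\\s*\"", x)
  asNum <- function(x) as.numeric(trimws(x))
  asStr <- function(x) .unquotePraat(sub("^\\s*\"(.*)\"\\s*$", "\\1", x))
  p <- 4L                                    # skip xmin, xmax, <exists>
  ntiers <- asNum(toks[p]); p <- p + 1L
  tiers <- vector("list", ntiers)
  for (t in seq_len(ntiers)) {
    cls <- asStr(toks[p]); p <- p + 1L
    nm <- asStr(toks[p]); p <- p + 1L
    p <- p + 2L                              # tier xmin, xmax
    nInt <- asNum(toks[p]); p <- p + 1L
    xmin <- xmax <- numeric(nInt)
    text <- character(nInt)
    for (k in seq_len(nInt)) {
      if (grepl("Point", cls)) {
        xmin[k] <- asNum(toks[p]); xmax[k] <- xmin[k]; p <- p + 1L
      } else {
        xmin[k] <- asNum(toks[p]); xmax[k] <- asNum(toks[p + 1L]); p <- p + 2L
      }
      text[k] <- asStr(toks[p]); p <- p + 1L
    }
    tiers[[t]] <- list(class = cls, name = nm,
                       xmin = xmin, xmax = xmax, text = text)
  }
  tiers
}

.parseTextGrid <- function(path) {
  lines <- .readPraatLines(path)
  if (!length(lines) || !grepl("ooTextFile", lines[1L]))
    srStop("parseError", "'%s' is not a Praat text file", path)
  if (any(grepl("xmin\\s*=", lines))) .parseLongTextGrid(lines)
  else .parseShortTextGrid(lines)
}

#' Read a Praat TextGrid interval tier as a SpeechSample
#'
#' Labels are normalized case-insensitively with surrounding whitespace
#' stripped; the tier must use the V/C/D/X labelling scheme. Empty labels
#' are mapped according to `emptyLabel` (silent pause by default). Gaps
#' between consecutive intervals are tolerated and filled according to
#' `gapPolicy`. Both the long ("ooTextFile" verbose) and short TextGrid
#' dialects are accepted, in UTF-8 or UTF-16.
#'
#' @param path path to the TextGrid file.
#' @param tier name of the interval tier holding the labels.
#' @param emptyLabel what to do with empty-labelled intervals: `"X"`
#'   (default, treat as silent pause) or `"error"`.
#' @param gapPolicy what to do with gaps between intervals: `"X"` (default,
#'   fill with a pause interval) or `"error"`.
#' @param sampleId,year,style,source metadata attached to the result;
#'   `sampleId` defaults to the file name without extension.
#' @return a [SpeechSample-class].
#' @export
readTextGrid <- function(path, tier = "segments",
                         emptyLabel = c("X", "error"),
                         gapPolicy = c("X", "error"),
                         sampleId = NULL, year = NA_integer_,
                         style = NA_character_, source = NA_character_) {
  emptyLabel <- match.arg(emptyLabel)
  gapPolicy <- match.arg(gapPolicy)
  if (!file.exists(path))
    srStop("ioError", "file '%s' does not exist", path)
  tiers <- .parseTextGrid(path)
  names(tiers) <- vapply(tiers, `[[`, "", "name")
  if (!(tier %in% names(tiers)))
    srStop("missingTier", "no tier named '%s' in '%s' (tiers: %s)",
           tier, path, paste(names(tiers), collapse = ", "))
  tg <- tiers[[tier]]
  if (!grepl("IntervalTier", tg$class))
    srStop("tierType", "tier '%s' is a %s, not an interval tier",
           tier, tg$class)
  lab <- normalizeLabel(tg$text)
  empty <- !nzchar(lab)
  if (any(empty)) {
    if (emptyLabel == "error")
      srStop("labellingError",
             "interval %d [%g, %g] has an empty label",
             which(empty)[1L], tg$xmin[which(empty)[1L]],
             tg$xmax[which(empty)[1L]])
    lab[empty] <- "X"
  }
  unk <- which(!(lab %in% .VALID_LABELS))
  if (length(unk))
    srStop("labellingError",
           "interval %d [%g, %g] has unknown label '%s'",
           unk[1L], tg$xmin[unk[1L]], tg$xmax[unk[1L]], tg$text[unk[1L]])
  start <- tg$xmin; end <- tg$xmax
  # drop zero-length degenerate entries, then fill gaps
  keep <- end > start + .TIME_TOL
  start <- start[keep]; end <- end[keep]; lab <- lab[keep]
  if (length(start) > 1L) {
    gaps <- which(start[-1L] > end[-length(end)] + .TIME_TOL)
    if (length(gaps)) {
      if (gapPolicy == "error")
        srStop("parseError", "gap between intervals %d and %d",
               gaps[1L], gaps[1L] + 1L)
      gstart <- end[gaps]; gend <- start[gaps + 1L]
      start <- c(start, gstart); end <- c(end, gend)
      lab <- c(lab, rep("X", length(gaps)))
      o <- order(start)
      start <- start[o]; end <- end[o]; lab <- lab[o]
    }
  }
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  speechSample(start, end, lab, sampleId = sampleId, year = year,
               style = style, source = source)
}

#' Write a SpeechSample as a long-format Praat TextGrid
#'
#' Emits a single interval tier. Times are written with six decimals, so a
#' read/write round trip preserves labels exactly and times to 1e-6 s.
#' An empty sample produces a TextGrid with one empty tier spanning \[0, 0\].
#'
#' @param sample a [SpeechSample-class].
#' @param path output file path.
#' @param tier name of the emitted interval tier.
#' @return `path`, invisibly.
#' @export
writeTextGrid <- function(sample, path, tier = "segments") {
  stopifnot(is(sample, "SpeechSample"))
  validObject(sample)
  iv <- intervals(sample)
  xmin <- if (nrow(iv)) min(iv$start) else 0
  xmax <- if (nrow(iv)) max(iv$end) else 0
  num <- function(x) sprintf("%.6f", x)
  out <- c('File type = "ooTextFile"',
           'Object class = "TextGrid"',
           '',
           sprintf('xmin = %s', num(xmin)),
           sprintf('xmax = %s', num(xmax)),
           'tiers? <exists>',
           'size = 1',
           'item []:',
           '    item [1]:',
           '        class = "IntervalTier"',
           sprintf('        name = "%s"', tier),
           sprintf('        xmin = %s', num(xmin)),
           sprintf('        xmax = %s', num(xmax)),
           sprintf('        intervals: size = %d', nrow(iv)))
  if (nrow(iv)) {
    body <- sprintf(paste0('        intervals [%d]:\n',
                           '            xmin = %s\n',
                           '            xmax = %s\n',
                           '            text = "%s"'),
                    seq_len(nrow(iv)), num(iv$start), num(iv$end), iv$label)
    out <- c(out, body)
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  tryCatch(writeLines(out, con),
           error = function(e) srStop("ioError", "cannot write '%s': %s",
                                      path, conditionMessage(e)))
  invisible(path)
}

#' Read and validate a corpus manifest
#'
#' A comma-separated table with header
#' `sample_id,year,annotation_path[,audio_path][,style]`.
#' Rows are returned sorted by year then sample id; duplicate ids and
#' unparseable years are errors.
#'
#' @param path path to the manifest CSV.
#' @return data.frame with columns `sample_id`, `year`, `annotation_path`
#'   and, when present, `audio_path` and `style`.
#' @export
readCorpusTable <- function(path) {
  if (!file.exists(path))
    srStop("ioError", "manifest '%s' does not exist", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("sample_id", "year", "annotation_path")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    srStop("parseError", "manifest missing column(s): %s",
           paste(miss, collapse = ", "))
  year <- suppressWarnings(as.integer(tab$year))
  bad <- which(is.na(year) & nzchar(tab$year))
  if (length(bad) || anyNA(year))
    srStop("parseError", "unparseable year '%s' in row %d",
           tab$year[c(bad, which(is.na(year)))[1L]],
           c(bad, which(is.na(year)))[1L])
  if (any(year < 1900L | year > 2100L))
    srStop("parseError", "year %d outside plausible range 1900-2100",
           year[which(year < 1900L | year > 2100L)[1L]])
  tab$year <- year
  dup <- tab$sample_id[duplicated(tab$sample_id)]
  if (length(dup))
    srStop("duplicateId", "duplicate sample_id '%s' in manifest", dup[1L])
  tab[order(tab$year, tab$sample_id), , drop = FALSE]
}

#' Write a corpus manifest
#'
#' @param table data.frame in the [readCorpusTable()] layout.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCorpusTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
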