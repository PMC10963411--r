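# Internal helpers: classed conditions and small numeric utilities.

# Tolerance for comparing interval time stamps (seconds).
.TIME_TOL <- 1e-6

# Signal a classed error so callers/tests can dispatch on the failure kind.
# class is a short tag, e.g. "undefinedMetric", "labellingError".
srStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(errorCondition(msg,
                      class = c(paste0("SpeechRhythm_", class),
                                "SpeechRhythm_error")))
}

srWarn <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  warning(warningCondition(msg,
                           class = c(paste0("SpeechRhythm_", class),
                                     "SpeechRhythm_warning")))
}

# Population (n denominator) standard deviation; stats::sd is the n-1 form.
popSd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# SD under the convention chosen for the stabilization module.
sdBy <- function(x, type = c("sample", "population")) {
  type <- match.arg(type)
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  if (type == "population") popSd(x) else stats::sd(x)
}

# Truncate (floor) to a number of decimals; guards against values such as
# 5.1 being represented as 5.0999... by allowing half an ulp of slack.
truncDecimals <- function(x, digits = 1L) {
  f <- 10^digits
  floor(x * f + 1e-9) / f
}

.VALID_LABELS <- c("V", "C", "D", "X")

# Case-insensitive, whitespace-stripped label normalization (idempotent).
normalizeLabel <- function(label) {
  toupper(trimws(label))
}
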