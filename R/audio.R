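# Schematic audio rendering of a labelled sample (tone for V, noise for C,
# silence for X/D) and minimal 16-bit PCM mono WAV I/O.
#
# The rendering is deliberately not a speech synthesizer: it produces a
# signal whose V/C/X structure is known exactly, so the acoustic segmenter
# can be validated against ground truth.

# Two-pole resonator (centre frequency f, bandwidth bw) applied recursively.
.resonate <- function(x, f, bw, sr) {
  r <- exp(-pi * bw / sr)
  theta <- 2 * pi * f / sr
  as.numeric(stats::filter(x, c(2 * r * cos(theta), -r^2),
                           method = "recursive"))
}

.applyRamp <- function(seg, nRamp) {
  n <- length(seg)
  if (n == 0L || nRamp == 0L) return(seg)
  k <- min(nRamp, floor(n / 2))
  if (k > 0L) {
    ramp <- 0.5 - 0.5 * cos(pi * seq_len(k) / k)
    seg[seq_len(k)] <- seg[seq_len(k)] * ramp
    seg[n - k + seq_len(k)] <- seg[n - k + seq_len(k)] * rev(ramp)
  }
  seg
}

#' Render a SpeechSample as schematic audio
#'
#' V intervals become a glottal-like pulse train at `f0` shaped by two
#' fixed resonances (about 500 and 1500 Hz, a schematic vowel); C intervals
#' become white noise `cSnrDb` below the vocalic RMS, with a fraction of C
#' intervals rendered silent to mimic stop closures; X and D intervals are
#' silent. Each rendered interval gets 5 ms raised-cosine amplitude ramps.
#'
#' @param sample a [SpeechSample-class].
#' @param sampleRate output sampling rate in Hz (default 16000).
#' @param f0 pulse-train fundamental in Hz (default 120).
#' @param cSnrDb consonant level below vowel RMS, in dB (default 10).
#' @param silentCFraction fraction of C intervals rendered as silence
#'   (stop closures; default 0.2).
#' @param seed seed for the noise and the silent-C draw; identical seeds
#'   give bit-identical waveforms.
#' @return list with `wave` (numeric vector in \[-1, 1\]) and `sampleRate`.
#' @export
synthesizeAudio <- function(sample, sampleRate = 16000, f0 = 120,
                            cSnrDb = 10, silentCFraction = 0.2, seed = 1L) {
  stopifnot(is(sample, "SpeechSample"))
  iv <- intervals(sample)
  if (nrow(iv) == 0L)
    srStop("emptyInput", "cannot synthesize audio from an empty sample")
  set.seed(seed)
  t0 <- min(iv$start)
  nTotal <- ceiling((max(iv$end) - t0) * sampleRate)
  wave <- numeric(nTotal)
  refRms <- 0.1
  cRms <- refRms * 10^(-cSnrDb / 20)
  nRamp <- round(0.005 * sampleRate)
  period <- sampleRate / f0
  for (i in seq_len(nrow(iv))) {
    i0 <- floor((iv$start[i] - t0) * sampleRate) + 1L
    i1 <- min(ceiling((iv$end[i] - t0) * sampleRate), nTotal)
    len <- i1 - i0 + 1L
    if (len <= 0L) next
    lab <- iv$label[i]
    if (lab == "V") {
      pulses <- numeric(len)
      at <- unique(pmax(1L, round(seq(1, len, by = period))))
      pulses[at] <- 1
      seg <- .resonate(.resonate(pulses, 500, 80, sampleRate),
                       1500, 120, sampleRate)
      rms <- sqrt(mean(seg^2))
      if (rms > 0) seg <- seg * (refRms / rms)
    } else if (lab == "C") {
      if (stats::runif(1) < silentCFraction) {
        seg <- numeric(len)
      } else {
        seg <- stats::rnorm(len)
        seg <- seg * (cRms / sqrt(mean(seg^2)))
      }
    } else {
      seg <- numeric(len)
    }
    wave[i0:i1] <- .applyRamp(seg, nRamp)
  }
  peak <- max(abs(wave))
  if (peak > 0.99) wave <- wave * (0.99 / peak)
  list(wave = wave, sampleRate = sampleRate)
}

#' Write a mono waveform as 16-bit PCM WAV
#'
#' @param wave numeric vector in \[-1, 1\] (values are clipped).
#' @param sampleRate sampling rate in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeWav <- function(wave, sampleRate, path) {
  pcm <- as.integer(round(pmax(-1, pmin(1, wave)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  dataBytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataBytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sampleRate), con, size = 4, endian = "little")
  writeBin(as.integer(sampleRate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataBytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path path to the WAV file.
#' @return list with `wave` (numeric in \[-1, 1\]) and `sampleRate`.
#' @export
readWav <- function(path) {
  if (!file.exists(path))
    srStop("ioError", "file '%s' does not exist", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    srStop("parseError", "'%s' is not a RIFF/WAV file", path)
  invisible(readBin(con, "integer", 1L, size = 4, endian = "little"))
  wavetag <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wavetag, "WAVE"))
    srStop("parseError", "'%s' is not a WAV file", path)
  sampleRate <- NULL; bits <- NULL; channels <- NULL; wave <- NULL
  repeat {
    tag <- readChar(con, 4L, useBytes = TRUE)
    if (length(tag) == 0L || !nzchar(tag)) break
    size <- readBin(con, "integer", 1L, size = 4, endian = "little")
    if (identical(tag, "fmt ")) {
      fmt <- readBin(con, "integer", 2L, size = 2, endian = "little")
      channels <- fmt[2L]
      sampleRate <- readBin(con, "integer", 1L, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1L, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1L, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1L, size = 2, endian = "little")
      extra <- size - 16L
      if (extra > 0L) invisible(readBin(con, "raw", extra))
      if (fmt[1L] != 1L || channels != 1L || bits != 16L)
        srStop("parseError",
               "'%s': only 16-bit PCM mono WAV is supported", path)
    } else if (identical(tag, "data")) {
      wave <- readBin(con, "integer", size / 2L, size = 2,
                      endian = "little", signed = TRUE) / 32768
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(wave) || is.null(sampleRate))
    srStop("parseError", "'%s': no PCM data found", path)
  list(wave = wave, sampleRate = sampleRate)
}
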