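#' Construct a Waveform
#'
#' @param samples numeric vector of finite amplitudes (nominally in \[-1, 1\]).
#' @param rateHz sample rate in Hz.
#' @param sourceId opaque identifier.
#' @return a [Waveform-class] object.
#' @export
Waveform <- function(samples, rateHz = 44100L, sourceId = NA_character_) {
  new("Waveform", samples = as.numeric(samples), rateHz = as.integer(rateHz),
      sourceId = as.character(sourceId))
}

#' Read a RIFF/WAVE file
#'
#' Reads PCM (16/24/32-bit) and IEEE-float RIFF/WAVE files. Multi-channel
#' input is averaged down to mono; integer PCM is rescaled to \[-1, 1\].
#' Inputs at rates other than 44100 Hz are rejected unless `resample = TRUE`,
#' in which case they are polyphase-resampled to 44100 Hz.
#'
#' @param path path to a `.wav` file.
#' @param resample logical; resample non-44100 Hz input instead of rejecting it.
#' @return a mono [Waveform-class].
#' @export
readWav <- function(path, resample = FALSE) {
  if (!file.exists(path)) .err("phonoPD_format_error", "file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) .err("phonoPD_format_error", "not a RIFF file: %s", path)
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) .err("phonoPD_format_error", "not a WAVE file: %s", path)

  fmt <- NULL
  dataRaw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(sz) == 0) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audioFormat = sum(as.integer(body[1:2]) * c(1, 256)),
        nChannels   = sum(as.integer(body[3:4]) * c(1, 256)),
        sampleRate  = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bitsPerSample = sum(as.integer(body[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      dataRaw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz)  # skip unknown chunk
    }
    if (sz %% 2 == 1) readBin(con, "raw", 1)  # chunks are word-aligned
    if (!is.null(fmt) && !is.null(dataRaw)) break
  }
  if (is.null(fmt) || is.null(dataRaw))
    .err("phonoPD_format_error", "malformed WAVE header (missing fmt/data chunk): %s", path)
  if (fmt$audioFormat == 65534) fmt$audioFormat <- 1  # WAVE_FORMAT_EXTENSIBLE: assume PCM
  bytes <- fmt$bitsPerSample / 8
  if (length(dataRaw) == 0) .err("phonoPD_empty_input_error", "zero-length audio: %s", path)
  x <- if (fmt$audioFormat == 1) {
    if (bytes == 2) {
      readBin(dataRaw, "integer", length(dataRaw) / 2, 2, signed = TRUE,
              endian = "little") / 32768
    } else if (bytes == 3) {
      m <- matrix(as.integer(dataRaw[seq_len(3 * (length(dataRaw) %/% 3))]), nrow = 3)
      v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      ifelse(v >= 8388608, v - 16777216, v) / 8388608
    } else if (bytes == 4) {
      readBin(dataRaw, "integer", length(dataRaw) / 4, 4, endian = "little") / 2147483648
    } else {
      .err("phonoPD_format_error", "unsupported PCM bit depth: %d", fmt$bitsPerSample)
    }
  } else if (fmt$audioFormat == 3) {
    readBin(dataRaw, "double", length(dataRaw) / bytes, bytes, endian = "little")
  } else {
    .err("phonoPD_format_error", "unsupported WAVE format code: %d", fmt$audioFormat)
  }
  if (length(x) == 0) .err("phonoPD_empty_input_error", "zero-length audio: %s", path)
  if (fmt$nChannels > 1) {
    n <- length(x) %/% fmt$nChannels
    x <- colMeans(matrix(x[seq_len(n * fmt$nChannels)], nrow = fmt$nChannels))
  }
  rate <- fmt$sampleRate
  if (rate != 44100) {
    if (!resample)
      .err("phonoPD_format_error",
           "sample rate %d Hz is not 44100 Hz (set resample = TRUE to convert)", rate)
    g <- .gcd(44100L, as.integer(rate))
    x <- as.numeric(signal::resample(x, 44100L / g, as.integer(rate) / g))
    rate <- 44100
  }
  Waveform(x, rate, path)
}

.gcd <- function(a, b) if (b == 0L) a else .gcd(b, a %% b)

#' Write a Waveform to a 16-bit PCM WAVE file
#'
#' @param w a [Waveform-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeWav <- function(w, path) {
  x <- pmax(-1, pmin(1, samples(w)))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  dataSize <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + dataSize, con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 1L), con, 2, endian = "little")          # PCM, mono
  writeBin(as.integer(sampleRate(w)), con, 4, endian = "little")
  writeBin(as.integer(sampleRate(w)) * 2L, con, 4, endian = "little")
  writeBin(c(2L, 16L), con, 2, endian = "little")         # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

#' Trim a recording to its first voiced second
#'
#' Frames the signal (25 ms frames, 10 ms hop by default), computes frame RMS
#' in dB relative to the loudest frame, and returns exactly one second of
#' audio starting at the first frame above the threshold. This automates the
#' leading/trailing-silence trim applied to phonation recordings before
#' feature extraction.
#'
#' @param w a [Waveform-class].
#' @param energyThresholdDb frames whose RMS falls below the peak frame RMS by
#'   more than this many dB are treated as silence (default -40).
#' @param frameMs analysis frame length in ms (hop is `frameMs * 0.4`).
#' @return a [Waveform-class] with exactly `sampleRate(w)` samples.
#' @export
trimToVoicedSecond <- function(w, energyThresholdDb = -40, frameMs = 25) {
  x <- samples(w)
  fs <- sampleRate(w)
  frameLen <- max(1L, round(frameMs / 1000 * fs))
  hop <- max(1L, round(0.4 * frameLen))  # 10 ms hop for the 25 ms default
  starts <- .frameStarts(length(x), frameLen, hop)
  if (length(starts) == 0)
    .err("phonoPD_insufficient_voicing_error",
         "recording shorter than one analysis frame")
  rms <- vapply(starts, function(s) .rmsDb(x[s:(s + frameLen - 1L)]), 0)
  voiced <- rms > max(rms) + energyThresholdDb
  if (!any(voiced))
    .err("phonoPD_insufficient_voicing_error", "no voiced frames found")
  first <- which(voiced)[1]
  # contiguous voiced run from the first voiced frame
  runEnd <- first
  while (runEnd < length(voiced) && voiced[runEnd + 1L]) runEnd <- runEnd + 1L
  startSample <- starts[first]
  voicedDur <- (starts[runEnd] + frameLen - startSample) / fs
  if (startSample + fs - 1L > length(x) || voicedDur < 1 - frameLen / fs)
    .err("phonoPD_insufficient_voicing_error",
         "voiced material too short: %.3f s measured, 1 s required", voicedDur)
  Waveform(x[startSample:(startSample + fs - 1L)], fs, sourceId(w))
}
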