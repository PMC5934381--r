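#' Calibratable mono waveform
#'
#' Container for mono audio used throughout the package: a numeric sample
#' vector in `[-1, 1]`, its sample rate, the bit depth used when exporting to
#' disk, and optional onset annotations (in seconds) recording where pulses or
#' stimulus replicates begin.
#'
#' @param samples Numeric vector of dimensionless amplitudes in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @param bit_depth Bit depth used for PCM export (default 16).
#' @param annotations Optional numeric vector of onset times in seconds.
#'
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, sample_rate = 44100, bit_depth = 16,
                     annotations = NULL) {
  if (!is.numeric(samples) || length(samples) < 1)
    stop("'samples' must be a non-empty numeric vector")
  if (!is_scalar(sample_rate) || sample_rate <= 0)
    stop("'sample_rate' must be a positive number")
  if (any(!is.finite(samples)))
    stop("'samples' contains non-finite values")
  if (max(abs(samples)) > 1 + 1e-9)
    stop("'samples' must lie within [-1, 1]")
  structure(
    list(samples = as.numeric(samples),
         sample_rate = sample_rate,
         bit_depth = bit_depth,
         annotations = annotations),
    class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.3f s), peak %.4f",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, max(abs(x$samples))))
  if (!is.null(x$annotations))
    cat(sprintf(", %d annotations", length(x$annotations)))
  cat("\n")
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param wave A [waveform()].
#' @return Duration in seconds.
#' @export
wave_duration <- function(wave) length(wave$samples) / wave$sample_rate

as_waveform <- function(x, sample_rate = 44100) {
  if (inherits(x, "waveform")) x else waveform(x, sample_rate)
}

# ---- RIFF/PCM WAV I/O ------------------------------------------------------
# Minimal mono PCM-16 reader/writer (RIFF little-endian).  Only the canonical
# 16-bit mono layout used by field recorders is supported; anything else is
# rejected rather than resampled.

#' Write a waveform to a 16-bit PCM WAV file
#'
#' @param wave A [waveform()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_wav <- function(wave, path) {
  stopifnot(inherits(wave, "waveform"))
  x <- wave$samples
  if (max(abs(x)) > 1) stop("samples exceed full scale; refusing to clip")
  pcm <- as.integer(round(pmax(pmin(x, 1 - 2^-15), -1) * 32768))
  pcm <- pmax(pmin(pcm, 32767L), -32768L)
  fs <- as.integer(round(wave$sample_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")         # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")     # byte rate
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path Path to a RIFF PCM WAV file (16-bit, mono).
#' @return A [waveform()] with samples scaled to `[-1, 1]`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, "integer", size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  fs <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (fmt[1] != 1) stop("only PCM WAV supported")
      channels <- fmt[2]
      fs <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", n = size - 16)
    } else if (id == "data") {
      if (is.null(bits)) stop("malformed WAV: data before fmt")
      if (bits != 16) stop("only 16-bit PCM supported")
      if (channels != 1) stop("only mono WAV supported")
      samples <- readBin(con, "integer", n = size / 2, size = 2,
                         signed = TRUE, endian = "little")
      break
    } else {
      readBin(con, "raw", n = size + size %% 2)
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  waveform(samples / 32768, sample_rate = fs, bit_depth = 16)
}
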