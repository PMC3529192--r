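## Minimal PCM WAV I/O.
##
## No audio package ships with the analysis environment, so the two RIFF
## routines the package needs (16-bit mono PCM read/write) are implemented
## directly. Only the canonical chunks are handled; anything else errors
## loudly rather than guessing.

#' Write a mono waveform to a 16-bit PCM WAV file
#'
#' @param waveform numeric vector in `[-1, 1]`; values outside are clipped
#'   with a warning.
#' @param path output file path
#' @param sample_rate sampling rate in Hz
#' @return `path`, invisibly
#' @export
write_wav <- function(waveform, path, sample_rate = 44100) {
  stopifnot(is.numeric(waveform), length(waveform) > 0, sample_rate > 0)
  if (any(abs(waveform) > 1)) {
    warning("waveform exceeds [-1, 1]; clipping")
    waveform <- pmin(1, pmax(-1, waveform))
  }
  pcm <- as.integer(round(waveform * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path WAV file path
#' @return list with `waveform` (numeric in `[-1, 1]`) and `sample_rate`
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  sample_rate <- NULL
  bits <- NULL
  channels <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV supported: ", path)
      channels <- fmt[2]
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      seek(con, size - 16, origin = "current")
    } else if (identical(id, "data")) {
      if (is.null(sample_rate)) stop("data chunk before fmt chunk in ", path)
      if (bits != 16L) stop("only 16-bit PCM supported: ", path)
      if (channels != 1L) stop("only mono WAV supported: ", path)
      pcm <- readBin(con, "integer", size / 2, size = 2,
                     signed = TRUE, endian = "little")
      return(list(waveform = pcm / 32767, sample_rate = sample_rate))
    } else {
      seek(con, size + size %% 2, origin = "current")
    }
  }
}
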