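#' Write a stereo waveform to a 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer for rendered stimulus blocks. Samples are expected
#' in [-1, 1] and are quantized to signed 16-bit integers.
#'
#' @param wave Numeric matrix, one column per channel (1 or 2 columns).
#' @param path Output file path.
#' @param sample_rate Samples per second.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, sample_rate = 48000) {
  if (is.vector(wave)) wave <- matrix(wave, ncol = 1)
  if (max(abs(wave)) > 1) stop("write_wav: samples must lie in [-1, 1]")
  n_ch <- ncol(wave)
  pcm <- as.integer(round(t(wave) * 32767))  # interleaved
  data_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * n_ch * 2L), con, size = 4, endian = "little")
  writeBin(as.integer(n_ch * 2L), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")           # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' Counterpart of [write_wav()]; reads only the uncompressed 16-bit PCM layout
#' that writer produces.
#'
#' @param path WAV file path.
#' @return List with `wave` (samples x channels matrix, values in [-1, 1]) and
#'   `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("read_wav: not a RIFF file")
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("read_wav: not a WAVE file")
  sample_rate <- NULL; n_ch <- NULL; wave <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("read_wav: only PCM supported")
      n_ch <- fmt[2]
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      blk <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (blk[2] != 16L) stop("read_wav: only 16-bit PCM supported")
    } else if (id == "data") {
      pcm <- readBin(con, "integer", sz / 2, size = 2, endian = "little")
      wave <- t(matrix(pcm / 32767, nrow = n_ch))
      break
    } else {
      readBin(con, "raw", sz)
    }
  }
  if (is.null(wave)) stop("read_wav: no data chunk found")
  list(wave = wave, sample_rate = sample_rate)
}
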