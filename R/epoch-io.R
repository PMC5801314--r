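#' Write an epoch set to a binary container file
#'
#' Single-file container with a documented layout: the magic string
#' `"MMNEPOCH1\n"`, a 4-byte little-endian integer giving the length of a
#' UTF-8 JSON header, the header itself (fields `subject_id`, `paradigm`,
#' `condition`, `channels`, `time_ms`, `sample_rate`, `dim`), and the voltage
#' payload as little-endian float64 in column-major order
#' (time x channel x trial). The round trip through [read_epochs()] is
#' bitwise lossless on the voltages.
#'
#' @param x An `epoch_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "epoch_set"))
  header <- jsonlite::toJSON(
    list(subject_id = x$subject_id, paradigm = x$paradigm,
         condition = x$condition, channels = x$channels,
         time_ms = x$time_ms, sample_rate = x$sample_rate,
         dim = dim(x$data)),
    auto_unbox = TRUE, digits = NA)
  hb <- charToRaw(as.character(header))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("MMNEPOCH1\n", con, eos = NULL)
  writeBin(length(hb), con, size = 4, endian = "little")
  writeBin(hb, con)
  writeBin(as.vector(x$data), con, size = 8, endian = "little")
  invisible(path)
}

#' Read an epoch set written by [write_epochs()]
#'
#' @param path Container file path.
#' @return An `epoch_set`.
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop("read_epochs: file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 10)
  if (!identical(magic, "MMNEPOCH1\n"))
    stop("read_epochs: not an epoch container (bad magic)")
  hlen <- readBin(con, "integer", 1, size = 4, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  if (is.null(header$channels))
    stop("read_epochs: corrupt container, channel table missing")
  if (is.null(header$dim) || is.null(header$time_ms))
    stop("read_epochs: corrupt container, dimensions or time axis missing")
  n <- prod(header$dim)
  dat <- readBin(con, "double", n, size = 8, endian = "little")
  if (length(dat) != n) stop("read_epochs: truncated payload")
  new_epoch_set(header$subject_id, header$paradigm, header$condition,
                header$channels, header$time_ms,
                array(dat, dim = header$dim), header$sample_rate)
}
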