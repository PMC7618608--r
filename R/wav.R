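# Minimal RIFF/WAVE I/O for mono or multi-channel PCM (16/24/32-bit integer
# and 32-bit IEEE float). Samples are exchanged as numeric vectors scaled to
# [-1, 1]; multi-channel input is mixed down to mono by averaging, since the
# segmentation front-end operates on a single pressure signal.

#' Read a WAV file
#'
#' @param path path to a RIFF/WAVE file (PCM 16/24/32-bit or float32).
#' @return list with `samples` (numeric in \[-1, 1\], mono) and `rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1L, 4L, endian = "little")
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      u16 <- function(o) sum(as.integer(body[o + 1:2]) * c(1, 256))
      u32 <- function(o) sum(as.integer(body[o + 1:4]) * c(1, 256, 65536, 16777216))
      fmt <- list(code = u16(0L), channels = as.integer(u16(2L)),
                  rate = as.integer(u32(4L)), bits = u16(14L))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      raw <- readBin(con, "raw", sz)
      samples <- wav_decode(raw, fmt)
    } else {
      readBin(con, "raw", sz)
    }
    if (sz %% 2L == 1L) readBin(con, "raw", 1L)  # chunk padding
    if (!is.null(samples) && !is.null(fmt)) break
  }
  if (is.null(samples)) stop("no data chunk in WAV file: ", path)
  if (fmt$channels > 1L) {
    samples <- rowMeans(matrix(samples, ncol = fmt$channels, byrow = TRUE))
  }
  list(samples = samples, rate = fmt$rate)
}

wav_decode <- function(raw, fmt) {
  if (fmt$code == 3L && fmt$bits == 32L) {
    return(readBin(raw, "numeric", length(raw) / 4L, size = 4L,
                   endian = "little"))
  }
  if (fmt$code != 1L) stop("unsupported WAV format code: ", fmt$code)
  if (fmt$bits == 16L) {
    x <- readBin(raw, "integer", length(raw) / 2L, size = 2L, signed = TRUE,
                 endian = "little")
    x / 32768
  } else if (fmt$bits == 24L) {
    b <- as.integer(raw)
    n <- length(b) %/% 3L
    v <- b[seq(1L, by = 3L, length.out = n)] +
      b[seq(2L, by = 3L, length.out = n)] * 256 +
      b[seq(3L, by = 3L, length.out = n)] * 65536
    v[v >= 8388608] <- v[v >= 8388608] - 16777216
    v / 8388608
  } else if (fmt$bits == 32L) {
    x <- readBin(raw, "integer", length(raw) / 4L, size = 4L,
                 endian = "little")
    x / 2147483648
  } else {
    stop("unsupported PCM bit depth: ", fmt$bits)
  }
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples numeric vector in \[-1, 1\]; values outside are clipped.
#' @param rate sample rate in Hz.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path) {
  x <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- length(x) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nbytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")          # PCM
  writeBin(1L, con, size = 2L, endian = "little")          # mono
  writeBin(as.integer(rate), con, size = 4L, endian = "little")
  writeBin(as.integer(rate * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(nbytes, con, size = 4L, endian = "little")
  writeBin(x, con, size = 2L, endian = "little")
  invisible(path)
}
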