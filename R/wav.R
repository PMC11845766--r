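# Minimal RIFF/WAVE PCM I/O.
#
# Supports the encodings found in lung-sound corpora: integer PCM at 8, 16,
# 24 and 32 bits and IEEE float32, mono or multi-channel (the first channel
# is kept). Samples are returned normalized to [-1, 1]. The writer emits
# 16-bit mono PCM, which is what the annotation-paired corpora use.

#' Read a PCM wav file
#'
#' @param path Path to a RIFF/WAVE file (integer PCM 8/16/24/32 bit or
#'   IEEE float32). For multi-channel files only the first channel is kept.
#' @return A list with `samples` (numeric vector in \[-1, 1\]) and
#'   `rate` (sampling rate in Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort(paste0("not a RIFF file: ", path))
  readBin(con, "integer", 1L, 4L, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort(paste0("not a WAVE file: ", path))

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz + sz %% 2L)
      fmt <- list(
        format    = sum(as.integer(body[1:2]) * c(1, 256)),
        channels  = sum(as.integer(body[3:4]) * c(1, 256)),
        rate      = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits      = sum(as.integer(body[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L == 1L) readBin(con, "raw", 1L)
    } else {
      readBin(con, "raw", sz + sz %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    abort(paste0("wav file missing fmt or data chunk: ", path))
  }
  if (!fmt$format %in% c(1L, 3L)) {
    abort(paste0("unsupported wav format code ", fmt$format, " in ", path))
  }

  n_bytes <- fmt$bits %/% 8L
  n_frames <- length(data_raw) %/% (n_bytes * fmt$channels)
  if (fmt$format == 3L) {
    if (fmt$bits != 32L) abort("float wav must be 32-bit")
    x <- readBin(data_raw, "double", n_frames * fmt$channels, size = 4L,
                 endian = "little")
  } else if (fmt$bits == 8L) {
    # 8-bit PCM is unsigned
    x <- (as.integer(readBin(data_raw, "raw", n_frames * fmt$channels)) -
            128) / 128
  } else if (fmt$bits %in% c(16L, 32L)) {
    x <- readBin(data_raw, "integer", n_frames * fmt$channels,
                 size = n_bytes, signed = TRUE, endian = "little") /
      2^(fmt$bits - 1)
  } else if (fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw[seq_len(n_frames * fmt$channels * 3L)]),
                nrow = 3L)
    v <- m[1L, ] + m[2L, ] * 256 + m[3L, ] * 65536
    v <- ifelse(v >= 2^23, v - 2^24, v)
    x <- v / 2^23
  } else {
    abort(paste0("unsupported wav bit depth ", fmt$bits))
  }
  if (fmt$channels > 1L) {
    x <- x[seq(1L, by = fmt$channels, length.out = n_frames)]
  }
  list(samples = as.numeric(x), rate = as.integer(fmt$rate))
}

#' Write a mono 16-bit PCM wav file
#'
#' @param samples Numeric vector in \[-1, 1\]; values outside are clipped.
#' @param rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path) {
  stopifnot(is.numeric(samples), length(samples) > 0L, rate > 0)
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  n_data <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_data), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")              # PCM
  writeBin(1L, con, size = 2L, endian = "little")              # mono
  writeBin(as.integer(rate), con, size = 4L, endian = "little")
  writeBin(as.integer(rate) * 2L, con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")              # block align
  writeBin(16L, con, size = 2L, endian = "little")             # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_data), con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
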