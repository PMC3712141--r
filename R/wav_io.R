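#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed PCM (16- or 24-bit) and IEEE
#' float32 data.  Integer samples are normalized to (-1, 1] by the container
#' full scale.  Multi-channel files are reduced to their first channel with a
#' warning.
#'
#' @param path Path to a `.wav` file.
#' @return A [waveform()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        code = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        fs = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little"))
    } else if (identical(id, "data")) {
      dat <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(dat)) break
  }
  if (is.null(fmt) || is.null(dat)) stop("malformed WAV: missing chunk")
  nch <- fmt$channels
  x <- switch(
    as.character(fmt$bits),
    "16" = {
      if (fmt$code != 1) stop("unsupported 16-bit format code ", fmt$code)
      readBin(dat, "integer", length(dat) %/% 2, 2, signed = TRUE,
              endian = "little") / 32768
    },
    "24" = {
      if (fmt$code != 1) stop("unsupported 24-bit format code ", fmt$code)
      b <- as.integer(dat)
      n3 <- length(b) %/% 3
      i <- 3 * (seq_len(n3) - 1)
      v <- b[i + 1] + 256 * b[i + 2] + 65536 * b[i + 3]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    "32" = {
      if (fmt$code != 3) stop("only float32 (format 3) supported at 32 bit")
      readBin(dat, "double", length(dat) %/% 4, 4, endian = "little")
    },
    stop("unsupported bit depth: ", fmt$bits))
  if (nch > 1) {
    warning("multi-channel WAV; taking the first channel")
    x <- x[seq(1, length(x), by = nch)]
  }
  waveform(x, fmt$fs)
}

#' Write a mono WAV file
#'
#' Writes uncompressed PCM16/PCM24 or IEEE float32.  In integer modes every
#' `|sample|` must be `<= 1` (the data would otherwise clip silently); float
#' mode accepts any amplitude.
#'
#' @param wave A [waveform()].
#' @param path Output path.
#' @param bits One of 16, 24 (PCM) or 32 (float).
#' @return The path, invisibly.
#' @export
write_wav <- function(wave, path, bits = 16) {
  stopifnot(inherits(wave, "Waveform"), bits %in% c(16, 24, 32))
  x <- wave$samples
  if (bits != 32 && max(abs(x)) > 1)
    stop("samples exceed full scale; use bits = 32 (float) or rescale")
  fs <- as.integer(round(wave$fs))
  n <- length(x)
  bytes_per <- bits %/% 8
  data_sz <- n * bytes_per
  fmt_code <- if (bits == 32) 3L else 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_sz), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")            # mono
  writeBin(fs, con, 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, 4, endian = "little")
  if (bits == 16) {
    v <- as.integer(pmin(32767, pmax(-32768, round(x * 32768))))
    writeBin(v, con, 2, endian = "little")
  } else if (bits == 24) {
    v <- round(x * 8388608)
    v <- pmin(8388607, pmax(-8388608, v))
    v <- ifelse(v < 0, v + 16777216, v)
    raw3 <- as.raw(rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256))
    writeBin(raw3, con)
  } else {
    writeBin(x, con, 4, endian = "little")
  }
  invisible(path)
}
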