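# RIFF/WAVE reading and writing.
#
# Only the two dialects used in practice by the acquisition software and by
# lossless fixtures are supported: 16-bit integer PCM (format tag 1) and
# 32-bit IEEE float (format tag 3). Multichannel files are accepted; the
# first channel is used (the sensing device is single-sensor).

#' Read a RIFF/WAVE file
#'
#' Parses a WAVE file and returns a [recording()] with samples scaled to
#' real values in \[-1, 1\] regardless of the on-disk encoding. 16-bit PCM
#' samples are divided by 32768; float samples are taken as stored. The
#' sampling rate is taken from the format chunk. For multichannel files the
#' first channel is used and a warning is issued.
#'
#' @param path Path to a readable WAVE file.
#' @param recording_id,subject_id Identifiers for the returned recording;
#'   `recording_id` defaults to the file name without extension.
#' @return A `va_recording`.
#' @export
read_wave <- function(path, recording_id = NULL, subject_id = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop("not a RIFF/WAVE file (missing RIFF header): ", path, call. = FALSE)
  }
  readBin(con, "integer", 1, size = 4, endian = "little")  # overall size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file (missing WAVE id): ", path, call. = FALSE)
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(sz) == 0L) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      if (length(body) < 16L) stop("corrupt fmt chunk", call. = FALSE)
      fmt <- list(
        tag      = readBin(body[1:2], "integer", 1, size = 2, endian = "little", signed = FALSE),
        channels = readBin(body[3:4], "integer", 1, size = 2, endian = "little", signed = FALSE),
        fs       = readBin(body[5:8], "integer", 1, size = 4, endian = "little"),
        bits     = readBin(body[15:16], "integer", 1, size = 2, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      seek(con, sz + sz %% 2, origin = "current")  # skip unknown chunk (word aligned)
      next
    }
    if (sz %% 2 == 1L) readBin(con, "raw", 1)  # chunk padding byte
    if (!is.null(fmt) && !is.null(data_raw)) break
  }

  if (is.null(fmt)) stop("corrupt WAVE file: no fmt chunk", call. = FALSE)
  if (is.null(data_raw) || length(data_raw) == 0L) {
    stop("empty WAVE file: no audio data", call. = FALSE)
  }

  if (fmt$tag == 1L && fmt$bits == 16L) {
    vals <- readBin(data_raw, "integer", length(data_raw) %/% 2L,
                    size = 2, endian = "little") / 32768
  } else if (fmt$tag == 3L && fmt$bits == 32L) {
    vals <- readBin(data_raw, "double", length(data_raw) %/% 4L,
                    size = 4, endian = "little")
  } else {
    stop(sprintf("unsupported WAVE encoding (format tag %d, %d bit)",
                 fmt$tag, fmt$bits), call. = FALSE)
  }
  if (length(vals) == 0L) stop("empty WAVE file: zero-length audio", call. = FALSE)

  if (fmt$channels > 1L) {
    warning("multichannel WAVE file: using channel 1 of ", fmt$channels)
    vals <- vals[seq(1L, length(vals), by = fmt$channels)]
  }
  if (is.null(recording_id)) {
    recording_id <- sub("\\.[^.]*$", "", basename(path))
  }
  recording(vals, fs = fmt$fs, recording_id = recording_id,
            subject_id = subject_id)
}

#' Write a recording to a RIFF/WAVE file
#'
#' Writes mono WAVE. With `encoding = "pcm16"` amplitudes outside \[-1, 1\]
#' are clipped to full scale and a warning is recorded; `"float32"` stores
#' amplitudes losslessly (use this for synthetic fixtures whose click
#' components exceed full scale).
#'
#' @param rec A `va_recording`.
#' @param path Output file path.
#' @param encoding `"pcm16"` (default) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wave <- function(rec, path, encoding = c("pcm16", "float32")) {
  encoding <- match.arg(encoding)
  x <- .as_samples(rec)
  if (!all(is.finite(x))) stop("samples must be finite", call. = FALSE)
  fs <- .get_fs(rec)

  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path,
                                           call. = FALSE))
  on.exit(close(con))

  if (encoding == "pcm16") {
    if (any(x > 1 | x < -1)) {
      warning("amplitudes outside [-1, 1] clipped for pcm16 encoding")
      x <- pmin(pmax(x, -1), 1)
    }
    ints <- as.integer(round(x * 32768))
    ints[ints > 32767L] <- 32767L      # +1.0 maps to the largest code
    ints[ints < -32768L] <- -32768L
    bytes_per <- 2L; tag <- 1L; bits <- 16L
  } else {
    bytes_per <- 4L; tag <- 3L; bits <- 32L
  }

  n <- length(x)
  data_size <- n * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(tag, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # channels
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")          # block align
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (encoding == "pcm16") {
    writeBin(ints, con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}
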