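# Minimal RIFF/WAVE reader and writer. The installed stack has no WAV codec,
# and the format is simple enough that a readBin-based implementation is the
# dependable route: PCM integer (8/16/24/32-bit) and IEEE float (32/64-bit)
# chunks are supported, multi-channel input is averaged to mono, and output
# is canonical 16-bit PCM.

#' Read a WAV file into an audio recording
#'
#' Supports RIFF/WAVE files holding integer PCM (8, 16, 24 or 32 bit) or IEEE
#' float (32 or 64 bit) samples. Integer samples are rescaled to \[-1, 1\] by
#' the format's full scale; multi-channel files are averaged to a mono signal.
#'
#' @param path Path to a `.wav` file.
#' @param sound_kind,label,id Metadata attached to the returned recording;
#'   `id` defaults to the file name without extension.
#' @return An [audio_recording()].
#' @seealso [write_wav()]
#' @export
read_wav <- function(path, sound_kind = "heart", label = "unknown",
                     id = NULL) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("WAV file not found: %s", path),
                 class = "cpsound_not_found_error")
  }
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    rlang::abort(sprintf("Not a RIFF file: %s", path), class = "cpsound_format_error")
  }
  readBin(con, "integer", 1, 4, endian = "little") # overall size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    rlang::abort(sprintf("Not a WAVE file: %s", path), class = "cpsound_format_error")
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    tag <- readChar(con, 4, useBytes = TRUE)
    if (length(tag) == 0 || nchar(tag) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(size) == 0) break
    if (identical(tag, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        format   = readBin(body[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        channels = readBin(body[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        rate     = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits     = readBin(body[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
      if (fmt$format == 65534L && size >= 40) { # WAVE_FORMAT_EXTENSIBLE
        fmt$format <- readBin(body[25:26], "integer", 1, 2, signed = FALSE, endian = "little")
      }
    } else if (identical(tag, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + (size %% 2L)) # skip unknown chunk (word-aligned)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    rlang::abort(sprintf("Corrupt or incomplete WAV header: %s", path),
                 class = "cpsound_format_error")
  }

  x <- decode_wav_samples(data_raw, fmt)
  if (fmt$channels > 1) {
    x <- rowMeans(matrix(x, ncol = fmt$channels, byrow = TRUE))
  }
  if (is.null(id)) id <- sub("\\.[Ww][Aa][Vv]$", "", basename(path))
  audio_recording(x, fmt$rate, sound_kind = sound_kind, label = label, id = id)
}

decode_wav_samples <- function(raw, fmt) {
  if (fmt$format == 1L) {
    switch(as.character(fmt$bits),
      "8" = {
        u <- as.integer(raw)                      # unsigned bytes
        (u - 128) / 128
      },
      "16" = readBin(raw, "integer", length(raw) / 2, 2, signed = TRUE,
                     endian = "little") / 32768,
      "24" = {
        n <- length(raw) / 3
        b <- matrix(as.integer(raw), nrow = 3)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      },
      "32" = readBin(raw, "integer", length(raw) / 4, 4, endian = "little") / 2147483648,
      rlang::abort(sprintf("Unsupported PCM bit depth: %d", fmt$bits),
                   class = "cpsound_format_error")
    )
  } else if (fmt$format == 3L) {
    switch(as.character(fmt$bits),
      "32" = readBin(raw, "double", length(raw) / 4, 4, endian = "little"),
      "64" = readBin(raw, "double", length(raw) / 8, 8, endian = "little"),
      rlang::abort(sprintf("Unsupported float bit depth: %d", fmt$bits),
                   class = "cpsound_format_error")
    )
  } else {
    rlang::abort(sprintf("Unsupported WAV format code: %d", fmt$format),
                 class = "cpsound_format_error")
  }
}

#' Write an audio recording as 16-bit PCM WAV
#'
#' Amplitudes are quantized by the 16-bit full scale (values outside
#' \[-1, 1\] are clipped), so a write/read round trip moves any sample by at
#' most one least-significant bit (1/32768).
#'
#' @param rec An [audio_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  check_recording(rec)
  q <- as.integer(pmax(-32768, pmin(32767, round(rec$samples * 32768))))
  n_bytes <- length(q) * 2L
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")               # PCM
  writeBin(1L, con, size = 2, endian = "little")               # mono
  writeBin(as.integer(round(rec$rate)), con, size = 4, endian = "little")
  writeBin(as.integer(round(rec$rate)) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")               # block align
  writeBin(16L, con, size = 2, endian = "little")              # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(q, con, size = 2, endian = "little")
  invisible(path)
}
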