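#' Audio clip container
#'
#' A minimal mono audio container: a double vector of samples on the
#' \[-1, 1\] full scale plus a sampling rate. Every stage of the pipeline
#' consumes or produces `usv_audio` objects.
#'
#' @param samples Numeric vector of samples (full scale is +/- 1).
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `usv_audio`.
#' @examples
#' clip <- usv_audio(sin(2 * pi * 440 * seq(0, 0.01, by = 1 / 48000)), 48000)
#' audio_duration(clip)
#' @export
usv_audio <- function(samples, sample_rate) {
  stopifnot(is.numeric(samples), length(sample_rate) == 1L, sample_rate > 0)
  if (anyNA(samples)) stop("audio samples must not contain NA")
  structure(
    list(samples = as.double(samples), sample_rate = as.double(sample_rate)),
    class = "usv_audio"
  )
}

#' @export
print.usv_audio <- function(x, ...) {
  cat(sprintf(
    "<usv_audio: %.3f s @ %g Hz, peak %.3f>\n",
    audio_duration(x), x$sample_rate, max(abs(x$samples), 0)
  ))
  invisible(x)
}

#' Duration of an audio clip in seconds
#' @param clip A [usv_audio] object.
#' @export
audio_duration <- function(clip) {
  stopifnot(inherits(clip, "usv_audio"))
  length(clip$samples) / clip$sample_rate
}

#' Root-mean-square level of a clip
#' @param clip A [usv_audio] object.
#' @export
audio_rms <- function(clip) {
  stopifnot(inherits(clip, "usv_audio"))
  sqrt(mean(clip$samples^2))
}

#' Hard-limit a clip (clipping degradation)
#'
#' Simulates amplitude saturation of a recording chain: every sample is
#' hard-limited to `+/- clip_level` of full scale; samples already inside the
#' bound are unchanged. The operation is idempotent.
#'
#' @param clip A [usv_audio] object.
#' @param clip_level Saturation bound as a fraction of full scale, in (0, 1].
#' @return A clipped [usv_audio].
#' @export
apply_clipping <- function(clip, clip_level = 0.5) {
  stopifnot(inherits(clip, "usv_audio"))
  if (!is.numeric(clip_level) || length(clip_level) != 1L || clip_level <= 0) {
    stop("`clip_level` must be a positive fraction of full scale")
  }
  if (clip_level > 1) stop("`clip_level` must be <= 1 (full scale)")
  usv_audio(pmin(pmax(clip$samples, -clip_level), clip_level), clip$sample_rate)
}

#' Attenuate (or amplify) a clip by a gain in dB
#'
#' Scales the waveform by `10^(gain_db/20)`, so the RMS level moves by exactly
#' `gain_db` decibels. Negative gains produce the low-amplitude degradation
#' scenario.
#'
#' @param clip A [usv_audio] object.
#' @param gain_db Gain in dB; negative attenuates.
#' @return A scaled [usv_audio].
#' @export
apply_attenuation <- function(clip, gain_db) {
  stopifnot(inherits(clip, "usv_audio"), is.numeric(gain_db), length(gain_db) == 1L)
  usv_audio(clip$samples * 10^(gain_db / 20), clip$sample_rate)
}

#' Overlay one clip on another (overlaid-call degradation)
#'
#' Adds clip `b` sample-wise onto clip `a`, with `b` starting `offset` seconds
#' after the start of `a`. The offset must place `b` at least partially inside
#' `a`'s support; building a non-overlaid sequence must be done explicitly with
#' the scene builders instead. The output is extended if `b` runs past the end
#' of `a`.
#'
#' @param a,b [usv_audio] objects with identical sample rates.
#' @param offset Start of `b` relative to the start of `a`, in seconds. May be
#'   negative (then `a` is shifted into `b`'s frame and times re-zeroed).
#' @return A [usv_audio] containing the sample-wise sum.
#' @export
overlay_calls <- function(a, b, offset = 0) {
  stopifnot(inherits(a, "usv_audio"), inherits(b, "usv_audio"))
  if (a$sample_rate != b$sample_rate) stop("sample rates differ")
  sr <- a$sample_rate
  off <- round(offset * sr)
  if (off >= length(a$samples) || off + length(b$samples) <= 0) {
    stop("`offset` yields zero overlap between the two clips")
  }
  shift <- max(0L, -off)            # if b starts before a, shift a right
  start_b <- max(0L, off)
  n <- max(length(a$samples) + shift, start_b + length(b$samples))
  out <- numeric(n)
  out[shift + seq_along(a$samples)] <- a$samples
  idx <- start_b + seq_along(b$samples)
  out[idx] <- out[idx] + b$samples
  usv_audio(out, sr)
}

# ---- WAV I/O ----------------------------------------------------------------
# Minimal mono RIFF/WAVE support: 16-bit integer PCM (format 1) and 32-bit IEEE
# float (format 3). Sufficient for the pipeline's standard exchange format.

#' Write a clip as a mono WAV file
#'
#' @param clip A [usv_audio] object.
#' @param path Output file path.
#' @param bit_depth `"float32"` (IEEE float, exact round trip) or `"int16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path, bit_depth = c("float32", "int16")) {
  stopifnot(inherits(clip, "usv_audio"))
  bit_depth <- match.arg(bit_depth)
  sr <- as.integer(round(clip$sample_rate))
  n <- length(clip$samples)
  fmt <- if (bit_depth == "float32") 3L else 1L
  bytes_per <- if (bit_depth == "float32") 4L else 2L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                  # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(as.integer(sr * bytes_per), con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")           # block align
  writeBin(8L * bytes_per, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bit_depth == "float32") {
    writeBin(clip$samples, con, size = 4, endian = "little")
  } else {
    x <- as.integer(round(pmin(pmax(clip$samples, -1), 1) * 32767))
    writeBin(x, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Supports the files [write_wav()] produces: mono, 16-bit PCM or 32-bit IEEE
#' float, with standard chunk layout.
#'
#' @param path Path to a WAV file.
#' @return A [usv_audio] object.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  fmt <- NULL; sr <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk found in ", path)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), size = 2, endian = "little")
      ch <- readBin(con, integer(), size = 2, endian = "little")
      if (ch != 1L) stop("only mono WAV is supported")
      sr <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16) readBin(con, raw(), n = size - 16L)
    } else if (id == "data") {
      n_bytes <- size
      if (fmt == 3L && bits == 32L) {
        x <- readBin(con, numeric(), n = n_bytes / 4L, size = 4, endian = "little")
      } else if (fmt == 1L && bits == 16L) {
        x <- readBin(con, integer(), n = n_bytes / 2L, size = 2,
                     signed = TRUE, endian = "little") / 32767
      } else {
        stop("unsupported WAV encoding (format ", fmt, ", ", bits, " bit)")
      }
      return(usv_audio(x, sr))
    } else {
      readBin(con, raw(), n = size + (size %% 2L))   # skip unknown chunk
    }
  }
}
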