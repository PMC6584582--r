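# Audio containers, WAV I/O, normalization, resampling and segmentation:
# the front end of the detection pipeline.

SUPPORTED_RATES <- c(8000L, 16000L, 44100L)

#' Construct a mono audio clip
#'
#' The basic container for all audio in the package: a mono waveform with a
#' sample rate and free-form condition metadata (distance, device,
#' interference kind, source id).
#'
#' @param samples numeric vector of samples; amplitudes are expected in
#'   `[-1, 1]` (enforced after [peak_normalize()] and by the scene renderer,
#'   not here).
#' @param sample_rate_hz sampling rate in Hz; one of 8000, 16000, 44100.
#' @param meta named list of condition tags.
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, sample_rate_hz, meta = list()) {
  if (!is.numeric(samples)) stopf("samples must be numeric")
  if (!sample_rate_hz %in% SUPPORTED_RATES) {
    stopf("unsupported sample rate %s Hz (use 8000, 16000 or 44100)", sample_rate_hz)
  }
  structure(
    list(samples = as.numeric(samples),
         sample_rate_hz = as.integer(sample_rate_hz),
         meta = meta),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip: %.3f s @ %d Hz, peak %.3f>\n",
              length(x$samples) / x$sample_rate_hz, x$sample_rate_hz,
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' Duration of an audio clip in seconds
#' @param clip an `audio_clip`.
#' @return Duration in seconds.
#' @export
clip_duration <- function(clip) length(clip$samples) / clip$sample_rate_hz

#' Read a mono WAV file
#'
#' Supports uncompressed PCM16 and IEEE float32 mono files. Multi-channel
#' files and other encodings are rejected.
#'
#' @param path path to a `.wav` file.
#' @return An [audio_clip()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  size <- file.info(path)$size
  if (is.na(size) || size < 44) stopf("not a WAV file (too short): %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stopf("not a RIFF/WAVE file: %s", path)
  }
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) stopf("WAV file has no data chunk: %s", path)
    len <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", len)
      fmt <- list(
        tag      = readBin(raw[1:2], "integer", 1, size = 2, endian = "little", signed = FALSE),
        channels = readBin(raw[3:4], "integer", 1, size = 2, endian = "little", signed = FALSE),
        rate     = readBin(raw[5:8], "integer", 1, size = 4, endian = "little"),
        bits     = readBin(raw[15:16], "integer", 1, size = 2, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stopf("WAV data chunk precedes fmt chunk: %s", path)
      if (fmt$channels != 1) stopf("only mono WAV is supported (file has %d channels)", fmt$channels)
      if (fmt$tag == 1 && fmt$bits == 16) {
        n <- len %/% 2
        x <- readBin(con, "integer", n, size = 2, endian = "little") / 32768
      } else if (fmt$tag == 3 && fmt$bits == 32) {
        n <- len %/% 4
        x <- readBin(con, "double", n, size = 4, endian = "little")
      } else {
        stopf("unsupported WAV encoding (format tag %d, %d bit)", fmt$tag, fmt$bits)
      }
      return(audio_clip(x, fmt$rate, meta = list(path = path)))
    } else {
      invisible(readBin(con, "raw", len + (len %% 2)))
    }
  }
}

#' Write a mono WAV file
#'
#' @param clip an [audio_clip()].
#' @param path output path.
#' @param bits 16 for PCM16 (default) or 32 for IEEE float.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path, bits = 16) {
  stopifnot(inherits(clip, "audio_clip"), bits %in% c(16, 32))
  x <- clip$samples
  if (any(abs(x) > 1)) stopf("samples exceed [-1, 1]; normalize before writing")
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- length(x) * bits / 8
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + nbytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(as.integer(if (bits == 16) 1 else 3), con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(clip$sample_rate_hz, con, size = 4, endian = "little")
  writeBin(as.integer(clip$sample_rate_hz * bits / 8), con, size = 4, endian = "little")
  writeBin(as.integer(bits / 8), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  if (bits == 16) {
    q <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Peak-normalize a clip to the range [-1, 1]
#'
#' Divides by the maximum absolute sample so the peak is exactly 1. Silent
#' (all-zero) clips are returned unchanged.
#'
#' @param clip an [audio_clip()].
#' @return The normalized clip.
#' @export
peak_normalize <- function(clip) {
  stopifnot(inherits(clip, "audio_clip"))
  if (length(clip$samples) == 0) stopf("cannot normalize an empty clip")
  peak <- max(abs(clip$samples))
  if (peak > 0) clip$samples <- clip$samples / peak
  clip
}

# Windowed-sinc low-pass for rational-rate conversion; zero-phase by
# construction (the filter's group delay is compensated exactly).
resample_kernel <- function(p, q) {
  m <- max(p, q)
  L <- 80L * m + 1L                       # odd length; ~40 sinc lobes
  k <- seq_len(L) - 1L - (L - 1L) / 2
  fc <- 0.5 / m                           # cycles/sample on the upsampled grid
  h <- 2 * fc * ifelse(k == 0, 1, sin(2 * pi * fc * k) / (2 * pi * fc * k))
  t <- (seq_len(L) - 1) / (L - 1)
  h * (0.42 - 0.5 * cos(2 * pi * t) + 0.08 * cos(4 * pi * t)) * p  # Blackman
}

#' Band-limited resampling
#'
#' Polyphase resampling by the rational factor `target_hz / clip rate`:
#' zero-stuffing, a windowed-sinc low-pass at the tighter Nyquist limit, and
#' decimation, with the filter delay compensated so output and input are
#' time-aligned. The output has `round(n * p / q)` samples, so duration is
#' preserved within one sample period.
#'
#' @param clip an [audio_clip()].
#' @param target_hz target rate; one of 8000, 16000, 44100.
#' @return The resampled clip.
#' @export
resample_audio <- function(clip, target_hz) {
  stopifnot(inherits(clip, "audio_clip"))
  if (!is_count(target_hz) || target_hz <= 0) stopf("target_hz must be a positive integer")
  if (!target_hz %in% SUPPORTED_RATES) {
    stopf("unsupported target rate %s Hz (use 8000, 16000 or 44100)", target_hz)
  }
  from <- clip$sample_rate_hz
  if (target_hz == from) return(clip)
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(from, as.integer(target_hz))
  p <- as.integer(target_hz) %/% d
  q <- from %/% d
  x <- clip$samples
  n <- length(x)
  up <- numeric(n * p)
  up[seq(1L, n * p, by = p)] <- x
  h <- resample_kernel(p, q)
  c0 <- (length(h) - 1L) / 2
  conv <- if (length(up) > 2e6) {
    as.numeric(signal::fftfilt(h, c(up, numeric(length(h)))))
  } else {
    fft_conv(up, h)
  }
  m <- floor(n * p / q)
  y <- conv[c0 + 1L + (seq_len(m) - 1L) * q]
  audio_clip(pmax(-1, pmin(1, y)), target_hz, meta = clip$meta)
}

#' Cut a clip into fixed-length segments
#'
#' Non-overlapping 2.5 s segments by default; an overlapping hop can be
#' configured. A trailing remainder shorter than one segment is dropped, so
#' the number of segments is `floor((duration - segment_len)/hop) + 1`. A
#' clip shorter than one segment yields an empty stream with a warning.
#'
#' @param clip an [audio_clip()].
#' @param segment_len_s segment length in seconds (default 2.5).
#' @param hop_s hop between segment starts in seconds (default
#'   `segment_len_s`, i.e. non-overlapping).
#' @return A `segment_stream`: segment waveforms as rows of a matrix, with
#'   strictly increasing start times (seconds, half-open intervals
#'   `[start, start + segment_len_s)`).
#' @export
segment_audio <- function(clip, segment_len_s = 2.5, hop_s = segment_len_s) {
  stopifnot(inherits(clip, "audio_clip"))
  if (segment_len_s <= 0 || hop_s <= 0) stopf("segment_len_s and hop_s must be positive")
  fs <- clip$sample_rate_hz
  seg_n <- round(segment_len_s * fs)
  hop_n <- round(hop_s * fs)
  n <- length(clip$samples)
  if (n < seg_n) {
    warnf("clip (%.2f s) shorter than one segment (%.2f s); empty stream",
          n / fs, segment_len_s)
    k <- 0L
  } else {
    k <- (n - seg_n) %/% hop_n + 1L
  }
  starts <- (seq_len(k) - 1L) * hop_n
  mat <- matrix(0, nrow = k, ncol = seg_n)
  for (i in seq_len(k)) {
    mat[i, ] <- clip$samples[(starts[i] + 1L):(starts[i] + seg_n)]
  }
  structure(
    list(samples = mat, start_s = starts / fs,
         segment_len_s = segment_len_s, hop_s = hop_s,
         sample_rate_hz = fs, meta = clip$meta),
    class = "segment_stream"
  )
}

#' @export
print.segment_stream <- function(x, ...) {
  cat(sprintf("<segment_stream: %d x %.2f s segments @ %d Hz, hop %.2f s>\n",
              nrow(x$samples), x$segment_len_s, x$sample_rate_hz, x$hop_s))
  invisible(x)
}

#' Number of segments in a stream
#' @param stream a `segment_stream`.
#' @return Integer count.
#' @export
n_segments <- function(stream) nrow(stream$samples)

#' Extract one segment as an audio clip
#' @param stream a `segment_stream`.
#' @param i segment index.
#' @return An [audio_clip()].
#' @export
get_segment <- function(stream, i) {
  audio_clip(stream$samples[i, ], stream$sample_rate_hz, meta = stream$meta)
}
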