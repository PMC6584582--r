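# FMCW chirp synchronization for over-the-air benchmark experiments: a
# linear frequency sweep with a sharp autocorrelation peak is prepended to
# each played clip; cross-correlating the recording with the chirp
# recovers the exact timestamp of every clip so it can be extracted and
# fed to the classifier.

#' Generate an FMCW chirp template
#'
#' Linear instantaneous-frequency sweep from `f_start_hz` to `f_end_hz`
#' with Hann-tapered edges (10 per cent of the duration each side) and unit
#' peak amplitude. The default 500-4000 Hz band sits inside telephony
#' bandwidth so 8 kHz material can be synchronized too.
#'
#' @param f_start_hz,f_end_hz sweep band; `f_start < f_end <= Nyquist`.
#' @param duration_s chirp length (default 0.1 s).
#' @param sample_rate_hz sampling rate.
#' @return A `chirp_template` (also a valid [audio_clip()]).
#' @export
make_chirp <- function(f_start_hz = 500, f_end_hz = 4000, duration_s = 0.1,
                       sample_rate_hz = 16000) {
  if (duration_s <= 0) stopf("duration_s must be positive")
  if (!(f_start_hz < f_end_hz)) stopf("f_start_hz must be < f_end_hz")
  if (f_end_hz > sample_rate_hz / 2) stopf("f_end_hz exceeds Nyquist")
  fs <- sample_rate_hz
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  phase <- 2 * pi * (f_start_hz * t + (f_end_hz - f_start_hz) / (2 * duration_s) * t^2)
  x <- sin(phase)
  taper_n <- max(2L, round(0.1 * n))
  ramp <- 0.5 * (1 - cos(pi * (seq_len(taper_n) - 1) / (taper_n - 1)))
  x[seq_len(taper_n)] <- x[seq_len(taper_n)] * ramp
  x[n - seq_len(taper_n) + 1L] <- x[n - seq_len(taper_n) + 1L] * ramp
  clip <- audio_clip(x / max(abs(x)), fs,
                     meta = list(f_start_hz = f_start_hz, f_end_hz = f_end_hz,
                                 duration_s = duration_s))
  class(clip) <- c("chirp_template", "audio_clip")
  clip
}

#' Locate chirp onsets by normalized cross-correlation
#'
#' The recording is cross-correlated with the template; both the template
#' and each recording window are unit-energy normalized, so the
#' correlation is level-independent and the threshold is an absolute
#' similarity in `[0, 1]`. Peaks above `threshold` are picked greedily
#' (strongest first) subject to a minimum separation.
#'
#' @param recording [audio_clip()] at the template sample rate.
#' @param template a [make_chirp()] template.
#' @param min_separation_s minimum spacing between accepted onsets
#'   (default: chirp duration + 2.5 s, one clip slot).
#' @param threshold correlation threshold (default 0.5).
#' @return Numeric vector of onset times in seconds, sorted ascending
#'   (empty if nothing crosses the threshold).
#' @export
locate_chirps <- function(recording, template, min_separation_s = NULL,
                          threshold = 0.5) {
  stopifnot(inherits(recording, "audio_clip"))
  if (recording$sample_rate_hz != template$sample_rate_hz) {
    stopf("recording rate %d Hz differs from template rate %d Hz",
          recording$sample_rate_hz, template$sample_rate_hz)
  }
  fs <- recording$sample_rate_hz
  h <- template$samples
  m <- length(h)
  x <- recording$samples
  n <- length(x)
  if (n < m) return(numeric(0))
  if (is.null(min_separation_s)) min_separation_s <- length(h) / fs + 2.5
  # numerator: correlation of x with h at every window start
  num <- fft_conv(x, rev(h))[m:n]
  # denominator: window energy via running sums
  cs <- cumsum(c(0, x^2))
  win_e <- cs[(m + 1):(n + 1)] - cs[1:(n - m + 1)]
  denom <- sqrt(pmax(win_e, 1e-300)) * sqrt(sum(h^2))
  corr <- num / denom
  corr[win_e < 1e-12] <- 0
  cand <- which(corr >= threshold)
  if (length(cand) == 0) return(numeric(0))
  cand <- cand[order(corr[cand], decreasing = TRUE)]
  min_sep_n <- round(min_separation_s * fs)
  accepted <- integer(0)
  for (i in cand) {
    if (all(abs(i - accepted) >= min_sep_n)) accepted <- c(accepted, i)
  }
  sort((accepted - 1) / fs)
}

#' Extract the clips that follow located chirps
#'
#' Clip `i` is `recording[onset_i + chirp_duration, onset_i +
#' chirp_duration + clip_len_s)`. Clips that would extend past the end of
#' the recording are dropped with a warning.
#'
#' @param recording [audio_clip()].
#' @param onsets_s chirp onsets from [locate_chirps()].
#' @param chirp_duration_s duration of the prepended chirp.
#' @param clip_len_s clip length (default 2.5 s).
#' @return List of [audio_clip()]s.
#' @export
extract_clips <- function(recording, onsets_s, chirp_duration_s, clip_len_s = 2.5) {
  stopifnot(inherits(recording, "audio_clip"))
  fs <- recording$sample_rate_hz
  n <- length(recording$samples)
  out <- list()
  for (on in onsets_s) {
    i0 <- round((on + chirp_duration_s) * fs)
    i1 <- i0 + round(clip_len_s * fs)
    if (i1 > n) {
      warnf("clip at %.3f s extends past the recording end; dropped", on)
      next
    }
    out[[length(out) + 1L]] <- audio_clip(recording$samples[(i0 + 1):i1], fs,
                                          meta = list(onset_s = on))
  }
  out
}
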