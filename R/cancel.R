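# Self-interference cancellation: a device playing soundscapes or podcasts
# while listening can subtract its own known transmission from the
# recording with a Sign-Data LMS adaptive filter before featurization.

#' Sign-Data LMS configuration
#'
#' @param n_weights number of filter taps (default 100). At 16 kHz this
#'   models echo-path delays up to 6.25 ms; longer delays must be removed
#'   by pre-alignment (see [locate_chirps()] or a known offset).
#' @param mu adaptation step size (default 0.05).
#' @return An `lms_config`.
#' @export
lms_config <- function(n_weights = 100, mu = 0.05) {
  if (!is_count(n_weights) || n_weights < 1) stopf("n_weights must be a positive integer")
  if (mu < 0) stopf("mu must be non-negative")
  structure(list(n_weights = as.integer(n_weights), mu = mu), class = "lms_config")
}

#' Cancel known playback from a recording
#'
#' Runs the Sign-Data LMS update sample by sample: the predicted echo is
#' the filter output over the last `n_weights` reference samples
#' (normalized by the running reference peak), the cleaned signal is the
#' prediction error, and the weights move by `mu * e * sign(x)` with
#' `sign(0) = 0`. Weights start at zero, so a zero reference or `mu = 0`
#' leaves the recording untouched. Fully deterministic.
#'
#' The reference must already be time-aligned with the recording to within
#' `n_weights` samples; alignment is the caller's job.
#'
#' @param received [audio_clip()] of the microphone recording.
#' @param reference [audio_clip()] of the known transmission, same sample
#'   rate. If shorter than `received` it is zero-padded with a warning.
#' @param config an [lms_config()].
#' @return List with `cleaned` (an [audio_clip()]) and `final_weights`.
#' @export
lms_cancel <- function(received, reference, config = lms_config()) {
  stopifnot(inherits(received, "audio_clip"), inherits(reference, "audio_clip"))
  if (received$sample_rate_hz != reference$sample_rate_hz) {
    stopf("sample rates differ (%d vs %d Hz)",
          received$sample_rate_hz, reference$sample_rate_hz)
  }
  r <- reference$samples
  n <- length(received$samples)
  if (length(r) < n) {
    warnf("reference (%d samples) shorter than recording (%d); zero-padding",
          length(r), n)
    r <- c(r, numeric(n - length(r)))
  }
  out <- lms_sign_data(received$samples, r[seq_len(n)], config$n_weights, config$mu)
  list(cleaned = audio_clip(pmax(-1, pmin(1, out$cleaned)),
                            received$sample_rate_hz, meta = received$meta),
       final_weights = out$weights)
}

#' Detection accuracy with and without playback cancellation
#'
#' Renders a scene, adds the device's own playback (a delayed, attenuated
#' copy of a known reference track), and classifies its 2.5 s segments
#' twice: directly, and after Sign-Data LMS cancellation using the known
#' reference. The primary `accuracy_*` figures are detection accuracy on
#' the played agonal clips (the fraction of gasp-bearing segments
#' classified positive); whole-stream per-segment accuracy is reported
#' alongside as `segment_accuracy_*`. When the playback gain is zero the
#' two paths are bit-identical.
#'
#' @param spec a [scene_spec()] (the acoustic scene without playback).
#' @param playback [audio_clip()] the device transmits, at the scene rate;
#'   recycled or truncated to the scene duration.
#' @param featurizer fitted `featurizer_model`.
#' @param detector fitted `detector_model`.
#' @param playback_gain amplitude of the playback echo as received at the
#'   microphone (0 disables playback).
#' @param delay_samples echo-path delay in samples (< `n_weights`).
#' @param config an [lms_config()].
#' @param threshold probability threshold (default the detector's).
#' @return List with `accuracy_with` / `accuracy_without` (played-clip
#'   detection accuracy; `NA` if the scene has no gasps),
#'   `segment_accuracy_with` / `segment_accuracy_without`, per-segment
#'   predictions and the ground-truth labels.
#' @export
evaluate_cancellation <- function(spec, playback, featurizer, detector,
                                  playback_gain = 0.5, delay_samples = 10,
                                  config = lms_config(),
                                  threshold = detector$threshold) {
  rendered <- render_scene(spec)
  clip <- rendered$clip
  n <- length(clip$samples)
  ref <- rep_len(playback$samples, n)
  echo <- c(numeric(delay_samples), ref)[seq_len(n)] * playback_gain
  mixed <- clip$samples + echo
  pk <- max(abs(mixed))
  scale <- if (pk > 1) 1 / pk else 1
  received <- audio_clip(mixed * scale, clip$sample_rate_hz)
  reference <- audio_clip(ref, clip$sample_rate_hz)

  classify <- function(c0) {
    stream <- segment_audio(c0)
    pred <- predict_detector(detector, embed_segments(stream, featurizer),
                             threshold = threshold)
    pred$start_s <- stream$start_s
    pred
  }
  without <- classify(received)
  cleaned <- lms_cancel(received, reference, config)$cleaned
  with_c <- classify(cleaned)
  truth_lab <- segment_labels(rendered$truth, without$start_s, 2.5)
  pos <- which(truth_lab)
  det_acc <- function(pred) if (length(pos)) mean(pred$label[pos]) else NA_real_
  list(
    accuracy_without = det_acc(without),
    accuracy_with = det_acc(with_c),
    segment_accuracy_without = mean(without$label == truth_lab),
    segment_accuracy_with = mean(with_c$label == truth_lab),
    pred_without = without, pred_with = with_c, labels = truth_lab
  )
}
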