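# Metrics and experiment harness: empirical ROC/AUC, Wald binomial
# intervals for operating points, streaming false-positive accounting and
# the benchmark condition grid (distance x interference x cancellation).

#' Empirical ROC curve and AUC
#'
#' Threshold sweep over the unique scores (ties grouped), AUC by the
#' trapezoid rule. Invariant under strictly monotone transforms of the
#' scores.
#'
#' @param scores numeric scores, larger = more agonal-like.
#' @param labels logical or 0/1 truth.
#' @return List with `roc` (data.frame `threshold`, `fpr`, `tpr`,
#'   monotone non-decreasing) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.logical(labels)
  if (length(scores) != length(y)) stopf("scores and labels disagree in length")
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) stopf("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; yo <- y[o]
  tp <- cumsum(yo); fp <- cumsum(!yo)
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tied block
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(roc = data.frame(threshold = c(Inf, s[last]), fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Wald (normal-approximation) binomial confidence interval
#'
#' `p_hat +/- z * sqrt(p_hat (1 - p_hat) / n)`, clipped to `[0, 1]`.
#'
#' @param p_hat observed proportion.
#' @param n number of trials (>= 1).
#' @param z normal quantile (default 1.96 for 95 per cent).
#' @return Numeric `c(lo, hi)`.
#' @export
wald_ci <- function(p_hat, n, z = 1.96) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) stopf("n must be >= 1")
  if (p_hat < 0 || p_hat > 1) stopf("p_hat must be in [0, 1]")
  se <- sqrt(p_hat * (1 - p_hat) / n)
  c(max(0, p_hat - z * se), min(1, p_hat + z * se))
}

#' Streaming false-positive rate in percent
#'
#' `100 * false positives / negative segments`, rounded half-up to five
#' decimal places (the convention used for streaming rates). Called either
#' with two aligned label streams, or with two scalar counts
#' (`fp_rate(fp_count, n_negative)`).
#'
#' @param pred predicted labels (logical/0-1 stream), or a scalar
#'   false-positive count.
#' @param truth true labels (logical/0-1 stream), or a scalar count of
#'   negative segments.
#' @return Percent, rounded half-up to 5 decimals.
#' @export
fp_rate <- function(pred, truth) {
  if (length(pred) == 1 && length(truth) == 1 &&
      !is.logical(pred) && !is.logical(truth)) {
    fp <- as.numeric(pred); n_neg <- as.numeric(truth)
  } else {
    pred <- as.logical(pred); truth <- as.logical(truth)
    if (length(pred) != length(truth)) stopf("streams must be equal length")
    n_neg <- sum(!truth)
    fp <- sum(pred & !truth)
  }
  if (n_neg == 0) stopf("no negative segments")
  round_half_up(100 * fp / n_neg, 5)
}

#' Benchmark condition grid
#'
#' For every row of the condition grid, renders seeded scenes under that
#' condition (distance, optional interference, optional self-playback
#' with or without LMS cancellation), classifies the 2.5 s segments and
#' reports mean and standard deviation of detection accuracy across
#' scenes. Detection accuracy follows the played-clip convention: for
#' `clip_class = "agonal"` it is the fraction of played gasp clips whose
#' segment is classified positive; for `clip_class = "negative"` the
#' fraction of segments of a played negative-sound stream classified
#' negative.
#'
#' @param featurizer fitted `featurizer_model`.
#' @param detector fitted `detector_model`.
#' @param conditions data.frame with columns `distance_m`, `interference`
#'   (a kind or "none"), and optionally `clip_class` ("agonal" default, or
#'   "negative"), `cancellation` (logical) and `playback_dbfs` (`-Inf`
#'   for no playback).
#' @param n_scenes scenes per cell (default 5).
#' @param seed integer seed.
#' @param scene_duration_s scene length (default 30 s).
#' @return `conditions` with `accuracy_mean`, `accuracy_sd` and `n_scenes`
#'   columns appended (empty grid in, empty table out).
#' @export
benchmark_matrix <- function(featurizer, detector, conditions, n_scenes = 5,
                             seed = 1, scene_duration_s = 30) {
  conditions <- as.data.frame(conditions)
  if (nrow(conditions) == 0) {
    return(cbind(conditions,
                 data.frame(accuracy_mean = numeric(0), accuracy_sd = numeric(0),
                            n_scenes = integer(0))))
  }
  if (!"cancellation" %in% names(conditions)) conditions$cancellation <- FALSE
  if (!"playback_dbfs" %in% names(conditions)) conditions$playback_dbfs <- -Inf
  if (!"clip_class" %in% names(conditions)) conditions$clip_class <- "agonal"
  conditions$interference <- as.character(conditions$interference)
  conditions$clip_class <- as.character(conditions$clip_class)
  acc_mean <- acc_sd <- numeric(nrow(conditions))
  for (r in seq_len(nrow(conditions))) {
    cc <- conditions[r, ]
    accs <- vapply(seq_len(n_scenes), function(i) {
      sseed <- derive_seed(seed, r * 1000L + i)
      spec <- benchmark_scene_spec(scene_duration_s, cc$distance_m,
                                   cc$interference, sseed,
                                   positive = cc$clip_class == "agonal")
      if (is.finite(cc$playback_dbfs)) {
        playback <- make_interference("soundscape", scene_duration_s,
                                      spec$sample_rate_hz,
                                      seed = derive_seed(sseed, 77L))
        playback$samples <- playback$samples / max(rms(playback$samples), 1e-12) *
          dbfs_to_amp(cc$playback_dbfs)
        playback$samples <- pmax(-1, pmin(1, playback$samples))
        res <- evaluate_cancellation(spec, playback, featurizer, detector,
                                     playback_gain = 1)
        acc <- if (isTRUE(cc$cancellation)) res$accuracy_with else res$accuracy_without
        if (cc$clip_class == "negative") {
          pred <- if (isTRUE(cc$cancellation)) res$pred_with else res$pred_without
          acc <- mean(!pred$label)
        }
        acc
      } else {
        rendered <- render_scene(spec)
        clip <- rendered$clip
        if (cc$clip_class == "negative") {
          # played negative sounds: a sleep-audio track under the same
          # distance/noise conditions
          trk <- make_negative_track(
            NEGATIVE_KINDS[(i - 1L) %% length(NEGATIVE_KINDS) + 1L],
            scene_duration_s, sample_rate_hz = spec$sample_rate_hz,
            seed = derive_seed(sseed, 5L))
          clip$samples <- pmax(-1, pmin(1, clip$samples +
                                          trk$samples * 0.6 / cc$distance_m))
        }
        stream <- segment_audio(clip)
        pred <- predict_detector(detector, embed_segments(stream, featurizer))
        if (cc$clip_class == "agonal") {
          truth <- segment_labels(rendered$truth, stream$start_s)
          mean(pred$label[truth])
        } else {
          mean(!pred$label)
        }
      }
    }, numeric(1))
    acc_mean[r] <- mean(accs)
    acc_sd[r] <- stats::sd(accs)
  }
  cbind(conditions, data.frame(accuracy_mean = acc_mean, accuracy_sd = acc_sd,
                               n_scenes = n_scenes))
}

# a physiologic gasp train (gaps drawn from 11-18 s) for benchmark cells;
# positive = FALSE gives the same scene without events
benchmark_scene_spec <- function(duration_s, distance_m, interference, seed,
                                 positive = TRUE) {
  ev <- if (!positive) empty_events() else with_seed(derive_seed(seed, 1L), {
    onsets <- numeric(0)
    t <- stats::runif(1, 0.5, 2)
    while (t < duration_s - 2) {
      onsets <- c(onsets, t)
      t <- t + stats::runif(1, 11, 18)
    }
    gasp_events(onsets, duration_s = stats::runif(length(onsets), 0.6, 1.2),
                amplitude = stats::runif(length(onsets), 0.5, 0.8))
  })
  intf <- if (!is.null(interference) && !is.na(interference) && interference != "none") {
    data.frame(kind = interference, level_dbfs = -35)
  } else NULL
  scene_spec(duration_s, events = ev, interference = intf,
             distance_m = distance_m, noise_floor_dbfs = -50, seed = seed)
}

#' Run the full detection pipeline on an audio stream
#'
#' Segment (2.5 s windows) -> optional Sign-Data LMS cancellation of known
#' playback -> log-mel + PCA embedding -> RBF-SVM probability -> agonal
#' rate filter. Deterministic given fixed models and inputs.
#'
#' @param x an [audio_clip()] or a path to a WAV file.
#' @param featurizer fitted `featurizer_model`.
#' @param detector fitted `detector_model`.
#' @param config a [filter_config()].
#' @param reference optional [audio_clip()] of known self-playback; when
#'   given, [lms_cancel()] runs before segmentation.
#' @param lms an [lms_config()].
#' @param threshold probability threshold (default the detector's).
#' @param truth optional `ground_truth` for an evaluation report.
#' @return List with `predictions` (data.frame `start_s`, `prob`,
#'   `label`), `alarms` (an `alarm_trace`) and `report` (confusion matrix,
#'   sensitivity/specificity with Wald CIs and streaming FP rates; `NULL`
#'   without `truth`).
#' @export
run_pipeline <- function(x, featurizer, detector, config = filter_config(),
                         reference = NULL, lms = lms_config(),
                         threshold = detector$threshold, truth = NULL) {
  clip <- if (is.character(x)) read_wav(x) else x
  stopifnot(inherits(clip, "audio_clip"))
  if (clip$sample_rate_hz != featurizer$sample_rate_hz) {
    clip <- resample_audio(clip, featurizer$sample_rate_hz)
  }
  if (!is.null(reference)) {
    clip <- lms_cancel(clip, reference, lms)$cleaned
  }
  stream <- segment_audio(clip)
  pred <- predict_detector(detector, embed_segments(stream, featurizer),
                           threshold = threshold)
  predictions <- data.frame(start_s = stream$start_s, prob = pred$prob,
                            label = pred$label)
  alarms <- run_stream(predictions, config)
  report <- NULL
  if (!is.null(truth)) {
    lab <- segment_labels(truth, stream$start_s, stream$segment_len_s)
    tp <- sum(pred$label & lab); fn <- sum(!pred$label & lab)
    tn <- sum(!pred$label & !lab); fp <- sum(pred$label & !lab)
    report <- list(
      confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      sensitivity_ci = if (tp + fn > 0) wald_ci(tp / (tp + fn), tp + fn) else c(NA, NA),
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      specificity_ci = if (tn + fp > 0) wald_ci(tn / (tn + fp), tn + fp) else c(NA, NA),
      fp_rate_percent = if (tn + fp > 0) fp_rate(fp, tn + fp) else NA_real_,
      accuracy = mean(pred$label == lab)
    )
  }
  list(predictions = predictions, alarms = alarms, report = report)
}
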