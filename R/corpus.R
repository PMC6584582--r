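# Labeled training corpora assembled from synthetic scenes. Positive
# sources are gasp trains cut so that each 2.5 s segment starts near a gasp
# onset (mirroring how clinical clips are cut from the start of each agonal
# breath); negative sources cycle through the sleep-audio classes. Sources
# cycle through recording distances of 1, 3 and 6 m, and half of them
# receive a household interference track.

#' Generate a labeled synthetic training corpus
#'
#' Renders `n_per_class` positive (agonal gasp train) and `n_per_class`
#' negative (snore / breathing / hypopnea / apnea) scenes, segments them
#' into 2.5 s windows and computes flattened log-mel features and
#' ground-truth labels. Each scene is one source recording for grouped
#' cross-validation; with `augment_distances = TRUE` every scene is
#' rendered at all of `distances` and the variants share one `source_id`.
#'
#' @param n_per_class scenes per class.
#' @param scene_duration_s scene length (default 10 s = four segments).
#' @param sample_rate_hz sampling rate (default 16000).
#' @param seed integer seed.
#' @param distances recording distances in metres, cycled over sources
#'   (default 1, 3, 6).
#' @param interference_level_dbfs RMS level of the interference track given
#'   to every second source (default -35).
#' @param noise_floor_dbfs device-noise floor (default -50).
#' @param augment_distances render each source at every distance.
#' @param augment_cancellation give every third source an additional
#'   variant that has been mixed with self-playback (a soundscape track)
#'   and passed through the Sign-Data LMS canceller, so the classifier
#'   learns that cancellation residue is not agonal breathing.
#' @param params [mel_params()].
#' @return An `agonal_corpus`: list with `logmel` (segments x features),
#'   `labels`, `source_id`, `condition` (data.frame of distance and
#'   interference tags) and `start_s`.
#' @export
make_training_corpus <- function(n_per_class, scene_duration_s = 10,
                                 sample_rate_hz = 16000, seed = 1,
                                 distances = c(1, 3, 6),
                                 interference_level_dbfs = -35,
                                 noise_floor_dbfs = -50,
                                 augment_distances = FALSE,
                                 augment_cancellation = TRUE,
                                 params = mel_params()) {
  specs <- list()
  idx <- 0L
  neg_kinds <- NEGATIVE_KINDS
  intf_kinds <- INTERFERENCE_KINDS
  for (cls in c(TRUE, FALSE)) {
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      sseed <- derive_seed(seed, idx)
      dist_set <- if (augment_distances) distances else distances[(i - 1L) %% length(distances) + 1L]
      intf <- if (i %% 2L == 0L) {
        data.frame(kind = intf_kinds[(i %/% 2L - 1L) %% length(intf_kinds) + 1L],
                   level_dbfs = interference_level_dbfs)
      } else NULL
      events <- if (cls) {
        # one gasp per 2.5 s segment, at a random position inside it (the
        # embedding is position-sensitive, so training must cover every
        # within-segment placement); the jitter cap keeps >= 50% of the
        # gasp support inside its own segment
        with_seed(derive_seed(sseed, 1L), {
          k <- floor(scene_duration_s / 2.5)
          durs <- stats::runif(k, 0.6, 1.2)
          jit <- stats::runif(k, 0.05, 2.5 - durs - 0.05)  # gasp stays in its segment
          onsets <- (seq_len(k) - 1) * 2.5 + jit
          amps <- stats::runif(k, 0.4, 0.8)
          gasp_events(onsets, durs, amps)
        })
      } else {
        empty_events()
      }
      for (d in dist_set) {
        specs[[length(specs) + 1L]] <- list(
          spec = scene_spec(scene_duration_s, sample_rate_hz, events = events,
                            interference = intf, distance_m = d,
                            noise_floor_dbfs = noise_floor_dbfs, seed = sseed),
          source_id = sprintf("%s%03d", if (cls) "pos" else "neg", i),
          neg_kind = if (cls) NA_character_ else neg_kinds[(i - 1L) %% length(neg_kinds) + 1L],
          positive = cls, variant_i = i
        )
      }
    }
  }
  rows <- list(); labels <- logical(0); sid <- character(0)
  cond <- list(); starts <- numeric(0)
  for (s in specs) {
    spec <- s$spec
    if (!s$positive) {
      # negative scenes carry a sleep-audio track instead of gasp events
      trk <- make_negative_track(s$neg_kind, spec$duration_s,
                                 rate_per_min = 10 + (derive_seed(spec$seed, 7L) %% 11L),
                                 sample_rate_hz = spec$sample_rate_hz,
                                 seed = derive_seed(spec$seed, 2L))
      rendered <- render_scene(spec)
      amp <- with_seed(derive_seed(spec$seed, 3L), stats::runif(1, 0.4, 0.8))
      rendered$clip$samples <- rendered$clip$samples +
        trk$samples * amp / spec$distance_m
      pk <- max(abs(rendered$clip$samples))
      if (pk > 1) rendered$clip$samples <- rendered$clip$samples / pk
    } else {
      rendered <- render_scene(spec)
    }
    variants <- list(rendered$clip)
    if (augment_cancellation && (s$variant_i %% 3L == 0L)) {
      variants[[2L]] <- cancelled_variant(rendered$clip, spec$seed)
    }
    for (v in seq_along(variants)) {
      stream <- segment_audio(variants[[v]])
      lab <- segment_labels(rendered$truth, stream$start_s, stream$segment_len_s)
      rows[[length(rows) + 1L]] <- logmel_matrix(stream, params)
      labels <- c(labels, lab)
      sid <- c(sid, rep(s$source_id, length(lab)))
      starts <- c(starts, stream$start_s)
      cond[[length(cond) + 1L]] <- data.frame(
        distance_m = rep(spec$distance_m, length(lab)),
        interference = rep(if (is.null(spec$interference)) "none" else spec$interference$kind[1],
                           length(lab)),
        neg_kind = rep(if (is.na(s$neg_kind)) "none" else s$neg_kind, length(lab)),
        cancelled = rep(v == 2L, length(lab))
      )
    }
  }
  structure(
    list(logmel = do.call(rbind, rows), labels = labels, source_id = sid,
         condition = do.call(rbind, cond), start_s = starts,
         sample_rate_hz = sample_rate_hz, params = params, seed = seed),
    class = "agonal_corpus"
  )
}

# mix a rendered scene with delayed self-playback and run the LMS
# canceller; returns the cleaned clip (an augmentation condition)
cancelled_variant <- function(clip, seed, level_dbfs = -20, delay_samples = 10) {
  n <- length(clip$samples)
  fs <- clip$sample_rate_hz
  pb <- make_interference("soundscape", n / fs, fs, derive_seed(seed, 4242L))$samples
  pb <- pb / max(rms(pb), 1e-12) * dbfs_to_amp(level_dbfs)
  pb <- pmax(-1, pmin(1, pb))
  echo <- c(numeric(delay_samples), pb)[seq_len(n)]
  received <- audio_clip(pmax(-1, pmin(1, clip$samples + echo)), fs)
  lms_cancel(received, audio_clip(pb, fs))$cleaned
}

#' @export
print.agonal_corpus <- function(x, ...) {
  cat(sprintf("<agonal_corpus: %d segments (%d positive) from %d sources>\n",
              length(x$labels), sum(x$labels), length(unique(x$source_id))))
  invisible(x)
}
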