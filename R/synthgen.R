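# Seeded synthetic acoustic scenes: agonal gasp trains, sleep-disordered
# breathing negatives, household interference, distance attenuation and a
# Gaussian noise floor. These stand in for clinical 9-1-1 and sleep-lab
# recordings, which cannot be redistributed; the gasp template is an
# engineering surrogate (broadband burst, sharp attack / slow decay, with a
# low-frequency 80-150 Hz harmonic component), not a physiologically
# validated model.

EVENT_KINDS <- c("agonal_gasp", "snore_cycle", "breath_cycle", "apnea_gap")
NEGATIVE_KINDS <- c("snore", "normal_breath", "hypopnea", "central_apnea", "obstructive_apnea")
INTERFERENCE_KINDS <- c("speech_like", "traffic_like", "white", "soundscape")

#' Specify a synthetic acoustic scene
#'
#' A scene is a timeline of respiratory events mixed with interference
#' tracks, attenuated by distance and laid over a Gaussian noise floor. The
#' same spec (including its seed) always renders to a bit-identical
#' waveform.
#'
#' @param duration_s scene length in seconds.
#' @param sample_rate_hz sampling rate (default 16000).
#' @param events data.frame with columns `onset_s`, `kind` (one of
#'   `agonal_gasp`, `snore_cycle`, `breath_cycle`, `apnea_gap`),
#'   `duration_s`, `amplitude` (0-1, relative to the 1 m reference level).
#' @param interference data.frame with columns `kind` (one of
#'   `speech_like`, `traffic_like`, `white`, `soundscape`) and `level_dbfs`
#'   (RMS level relative to full scale).
#' @param distance_m source-microphone distance in metres (>= 0.1); events
#'   are scaled by `1/distance_m` relative to 1 m. Interference and noise
#'   floor are ambient and not distance-scaled.
#' @param noise_floor_dbfs RMS level of the additive Gaussian device-noise
#'   floor.
#' @param seed integer seed; every random component of the scene derives
#'   its own stream from it.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(duration_s, sample_rate_hz = 16000,
                       events = empty_events(), interference = NULL,
                       distance_m = 1, noise_floor_dbfs = -60, seed = 1) {
  if (duration_s <= 0) stopf("duration_s must be positive")
  if (distance_m < 0.1) stopf("distance_m must be >= 0.1")
  events <- as.data.frame(events)
  if (nrow(events)) {
    need <- c("onset_s", "kind", "duration_s", "amplitude")
    if (!all(need %in% names(events))) {
      stopf("events must have columns %s", paste(need, collapse = ", "))
    }
    if (!all(events$kind %in% EVENT_KINDS)) {
      stopf("unknown event kind(s): %s",
            paste(setdiff(events$kind, EVENT_KINDS), collapse = ", "))
    }
    if (is.unsorted(events$onset_s, strictly = TRUE)) {
      stopf("event onsets must be strictly increasing")
    }
    if (any(events$onset_s + events$duration_s > duration_s + 1e-9)) {
      stopf("all events must end within duration_s")
    }
    if (any(events$amplitude < 0 | events$amplitude > 1)) {
      stopf("event amplitudes must be in [0, 1]")
    }
    ag <- events[events$kind == "agonal_gasp", ]
    if (nrow(ag) > 1) {
      ends <- ag$onset_s + ag$duration_s
      if (any(ag$onset_s[-1] < ends[-nrow(ag)] - 1e-9)) {
        stopf("agonal gasps must not overlap")
      }
    }
  }
  if (!is.null(interference)) {
    interference <- as.data.frame(interference)
    if (!all(c("kind", "level_dbfs") %in% names(interference))) {
      stopf("interference must have columns kind, level_dbfs")
    }
    if (!all(interference$kind %in% INTERFERENCE_KINDS)) {
      stopf("unknown interference kind(s): %s",
            paste(setdiff(interference$kind, INTERFERENCE_KINDS), collapse = ", "))
    }
  }
  structure(
    list(duration_s = duration_s, sample_rate_hz = as.integer(sample_rate_hz),
         events = events, interference = interference,
         distance_m = distance_m, noise_floor_dbfs = noise_floor_dbfs,
         seed = as.integer(seed)),
    class = "scene_spec"
  )
}

#' Empty event table for a scene spec
#' @return A zero-row data.frame with the scene event columns.
#' @export
empty_events <- function() {
  data.frame(onset_s = numeric(0), kind = character(0),
             duration_s = numeric(0), amplitude = numeric(0))
}

#' Build an event table of agonal gasps at given onsets
#'
#' @param onsets_s gasp onset times in seconds.
#' @param duration_s gasp duration (default 1 s).
#' @param amplitude per-event amplitude (recycled).
#' @return An event data.frame for [scene_spec()].
#' @export
gasp_events <- function(onsets_s, duration_s = 1.0, amplitude = 0.6) {
  data.frame(onset_s = onsets_s, kind = "agonal_gasp",
             duration_s = duration_s, amplitude = amplitude)
}

#' Read a scene spec from YAML or JSON
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return A [scene_spec()].
#' @export
read_scene_spec <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stopf("yaml package required")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  scene_spec(
    duration_s = x$duration_s,
    sample_rate_hz = x$sample_rate_hz %||% 16000,
    events = if (!is.null(x$events)) as.data.frame(x$events) else empty_events(),
    interference = if (!is.null(x$interference)) as.data.frame(x$interference) else NULL,
    distance_m = x$distance_m %||% 1,
    noise_floor_dbfs = x$noise_floor_dbfs %||% -60,
    seed = x$seed %||% 1
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthesize one agonal gasp
#'
#' A broadband noise burst shaped by a sharp-attack (50 ms), slow-decay
#' (~400 ms time scale) envelope, mixed with a low-frequency harmonic
#' component whose fundamental is drawn from 80-150 Hz. Peak amplitude is 1
#' before any scene scaling.
#'
#' @param duration_s gasp length in seconds, in `[0.2, 2]`.
#' @param sample_rate_hz sampling rate.
#' @param seed integer seed; the waveform is deterministic given the seed.
#' @return An [audio_clip()].
#' @export
make_agonal_gasp <- function(duration_s, sample_rate_hz = 16000, seed = 1) {
  if (!is.numeric(duration_s) || duration_s < 0.2 || duration_s > 2.0) {
    stopf("duration_s must be in [0.2, 2.0]")
  }
  fs <- sample_rate_hz
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  with_seed(seed, {
    f0 <- runif(1, 80, 150)
    noise <- rnorm(n)
    # gentle band shaping of the burst: emphasize 200-2500 Hz
    bp <- signal::butter(2, c(200, 2500) / (fs / 2), type = "pass")
    noise <- as.numeric(signal::filter(bp, noise))
    harm <- sin(2 * pi * f0 * t + runif(1, 0, 2 * pi)) +
      0.5 * sin(2 * pi * 2 * f0 * t + runif(1, 0, 2 * pi))
    attack <- 0.05
    env <- ifelse(t < attack,
                  0.5 * (1 - cos(pi * t / attack)),
                  exp(-(t - attack) / 0.15))
    x <- (0.8 * noise / max(abs(noise)) + 0.5 * harm) * env
    audio_clip(x / max(abs(x)), fs, meta = list(kind = "agonal_gasp", f0 = f0))
  })
}

# one respiratory cycle: band-limited noise under a raised-cosine envelope;
# snores add a low-frequency palatal buzz
render_breath_cycle <- function(kind, burst_s, fs, f_buzz = 90) {
  n <- round(burst_s * fs)
  t <- (seq_len(n) - 1) / fs
  env <- 0.5 * (1 - cos(2 * pi * t / burst_s))
  noise <- rnorm(n)
  bp <- signal::butter(2, c(300, 1200) / (fs / 2), type = "pass")
  x <- as.numeric(signal::filter(bp, noise))
  x <- x / max(abs(x))
  if (kind == "snore") {
    buzz <- sign(sin(2 * pi * f_buzz * t)) * (0.6 + 0.4 * sin(2 * pi * 2 * f_buzz * t))
    x <- 0.4 * x + 0.8 * buzz
  }
  x * env
}

#' Synthesize a negative-class sleep-audio track
#'
#' Periodic respiratory cycles emulating the acoustic structure of
#' polysomnography classes: `snore` (low-frequency buzz), `normal_breath`
#' (band-limited breath noise), `hypopnea` (amplitude-reduced cycles in the
#' middle of the track), `central_apnea` (a silent gap of at least 10 s
#' with no respiratory effort), `obstructive_apnea` (a gap of the same
#' length containing weak residual struggle bursts).
#'
#' @param kind one of `snore`, `normal_breath`, `hypopnea`,
#'   `central_apnea`, `obstructive_apnea`.
#' @param duration_s track length (> 0).
#' @param rate_per_min respiratory rate, 6-30 cycles/min.
#' @param sample_rate_hz sampling rate.
#' @param seed integer seed.
#' @return An [audio_clip()] with peak amplitude 1.
#' @export
make_negative_track <- function(kind, duration_s, rate_per_min = 15,
                                sample_rate_hz = 16000, seed = 1) {
  if (!is.character(kind) || !kind %in% NEGATIVE_KINDS) {
    stopf("unknown negative-track kind: %s", paste(kind, collapse = ","))
  }
  if (!is.numeric(duration_s) || duration_s <= 0) stopf("duration_s must be positive")
  if (rate_per_min < 6 || rate_per_min > 30) stopf("rate_per_min must be in [6, 30]")
  fs <- sample_rate_hz
  n <- round(duration_s * fs)
  period_s <- 60 / rate_per_min
  burst_s <- min(0.3 * period_s, 1.2)
  cycle_kind <- if (kind == "snore") "snore" else "normal_breath"
  with_seed(seed, {
    f_buzz <- runif(1, 70, 110)
    x <- numeric(n)
    onsets <- seq(0, duration_s - burst_s, by = period_s)
    # apnea kinds carve a >= 10 s event out of the middle of the track
    gap <- NULL
    if (kind %in% c("central_apnea", "obstructive_apnea")) {
      gap_len <- min(duration_s, runif(1, 12, max(12, min(18, duration_s * 0.45))))
      gap_start <- (duration_s - gap_len) / 2
      gap <- c(gap_start, gap_start + gap_len)
    }
    for (on in onsets) {
      if (!is.null(gap) && on + burst_s > gap[1] && on < gap[2]) next
      amp <- runif(1, 0.85, 1)
      if (kind == "hypopnea" && on > duration_s / 3 && on < 2 * duration_s / 3) {
        amp <- amp * 0.2  # reduced-airflow cycles
      }
      cyc <- render_breath_cycle(cycle_kind, burst_s, fs, f_buzz) * amp
      i0 <- round(on * fs)
      idx <- (i0 + 1):min(n, i0 + length(cyc))
      x[idx] <- x[idx] + cyc[seq_along(idx)]
    }
    if (kind == "obstructive_apnea" && !is.null(gap)) {
      # residual struggle bursts at low amplitude during the occlusion
      for (on in seq(gap[1] + 1, gap[2] - 1, by = 2.5)) {
        cyc <- render_breath_cycle("normal_breath", 0.3, fs) * 0.06
        i0 <- round(on * fs)
        idx <- (i0 + 1):min(n, i0 + length(cyc))
        x[idx] <- x[idx] + cyc[seq_along(idx)]
      }
    }
    peak <- max(abs(x))
    if (peak > 0) x <- x / peak  # a short central apnea can be all gap
    audio_clip(x, fs, meta = list(kind = kind, rate_per_min = rate_per_min))
  })
}

#' Synthesize an interference track
#'
#' Surrogates for household and outdoor interferers: `speech_like`
#' (formant-band noise with syllabic-rate amplitude modulation),
#' `traffic_like` (low-pass rumble, > 80 per cent of power below 500 Hz,
#' with occasional transients), `white` (flat-spectrum noise), `soundscape`
#' (narrowband filtered noise, similar to a river-current sleep sound).
#'
#' @param kind one of `speech_like`, `traffic_like`, `white`, `soundscape`.
#' @param duration_s track length (> 0).
#' @param sample_rate_hz sampling rate.
#' @param seed integer seed.
#' @return An [audio_clip()] with peak amplitude 1.
#' @export
make_interference <- function(kind, duration_s, sample_rate_hz = 16000, seed = 1) {
  if (!is.character(kind) || !kind %in% INTERFERENCE_KINDS) {
    stopf("unknown interference kind: %s", paste(kind, collapse = ","))
  }
  if (!is.numeric(duration_s) || duration_s <= 0) stopf("duration_s must be positive")
  fs <- sample_rate_hz
  n <- round(duration_s * fs)
  with_seed(seed, {
    x <- switch(kind,
      white = rnorm(n),
      speech_like = {
        carrier <- as.numeric(signal::filter(
          signal::butter(3, c(300, 3000) / (fs / 2), type = "pass"), rnorm(n)))
        t <- (seq_len(n) - 1) / fs
        syllabic <- as.numeric(signal::filter(
          signal::butter(2, 6 / (fs / 2), type = "low"), rnorm(n)))
        syllabic <- syllabic / max(abs(syllabic))
        carrier * pmax(0, 0.3 + syllabic)^2
      },
      traffic_like = {
        rumble <- as.numeric(signal::filter(
          signal::butter(4, 150 / (fs / 2), type = "low"), rnorm(n)))
        bumps <- numeric(n)
        for (on in runif(max(1, round(duration_s / 4)), 0, max(0.01, duration_s - 0.3))) {
          m <- round(0.2 * fs)
          env <- exp(-(seq_len(m) - 1) / (0.04 * fs))
          th <- as.numeric(signal::filter(
            signal::butter(4, 300 / (fs / 2), type = "low"), rnorm(m))) * env
          i0 <- round(on * fs)
          idx <- (i0 + 1):min(n, i0 + m)
          bumps[idx] <- bumps[idx] + th[seq_along(idx)]
        }
        rumble / max(abs(rumble)) + 0.5 * if (max(abs(bumps)) > 0) bumps / max(abs(bumps)) else bumps
      },
      soundscape = as.numeric(signal::filter(
        signal::butter(3, c(800, 1400) / (fs / 2), type = "pass"), rnorm(n)))
    )
    audio_clip(x / max(abs(x)), fs, meta = list(kind = kind))
  })
}

render_event <- function(kind, duration_s, fs, seed) {
  switch(kind,
    agonal_gasp = make_agonal_gasp(duration_s, fs, seed)$samples,
    snore_cycle = with_seed(seed, {
      f <- runif(1, 70, 110)
      x <- render_breath_cycle("snore", duration_s, fs, f)
      x / max(abs(x))
    }),
    breath_cycle = with_seed(seed, {
      x <- render_breath_cycle("normal_breath", duration_s, fs)
      x / max(abs(x))
    }),
    apnea_gap = numeric(round(duration_s * fs))
  )
}

#' Render a scene spec to audio plus ground truth
#'
#' Events are rendered at their onsets with per-event seeds split from the
#' scene seed, scaled by `amplitude / distance_m`; interference tracks and
#' the Gaussian noise floor are added at their stated RMS dBFS levels. If
#' the mix would clip, the whole waveform is scaled down (never clipped)
#' and the scale factor recorded in `meta$mix_scale`.
#'
#' @param spec a [scene_spec()].
#' @return A list with `clip` (an [audio_clip()]) and `truth` (a
#'   `ground_truth`: the agonal event table plus the labeling rule; see
#'   [segment_labels()]).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  fs <- spec$sample_rate_hz
  n <- round(spec$duration_s * fs)
  x <- numeric(n)
  ev <- spec$events
  for (i in seq_len(nrow(ev))) {
    w <- render_event(ev$kind[i], ev$duration_s[i], fs, derive_seed(spec$seed, i)) *
      ev$amplitude[i] / spec$distance_m
    i0 <- round(ev$onset_s[i] * fs)
    idx <- (i0 + 1):min(n, i0 + length(w))
    x[idx] <- x[idx] + w[seq_along(idx)]
  }
  intf <- spec$interference
  for (j in seq_len(if (is.null(intf)) 0 else nrow(intf))) {
    trk <- make_interference(intf$kind[j], spec$duration_s, fs,
                             derive_seed(spec$seed, 1000L + j))$samples
    trk <- trk / max(rms(trk), 1e-12) * dbfs_to_amp(intf$level_dbfs[j])
    x <- x + trk[seq_len(n)]
  }
  if (is.finite(spec$noise_floor_dbfs)) {
    floor_amp <- dbfs_to_amp(spec$noise_floor_dbfs)
    x <- x + with_seed(derive_seed(spec$seed, 999L), rnorm(n, sd = floor_amp))
  }
  mix_scale <- 1
  peak <- max(abs(x))
  if (peak > 1) {
    mix_scale <- 1 / peak
    x <- x * mix_scale
  }
  truth <- structure(
    list(events = ev[ev$kind == "agonal_gasp",
                     c("onset_s", "duration_s", "kind"), drop = FALSE],
         duration_s = spec$duration_s),
    class = "ground_truth"
  )
  clip <- audio_clip(x, fs, meta = list(distance_m = spec$distance_m,
                                        seed = spec$seed, mix_scale = mix_scale))
  list(clip = clip, truth = truth)
}

#' Per-segment ground-truth labels
#'
#' A segment is labeled positive iff it overlaps at least half of some
#' agonal gasp's support (the overlap threshold is a fraction of the gasp
#' duration, not of the segment).
#'
#' @param truth a `ground_truth` from [render_scene()].
#' @param start_s segment start times (seconds).
#' @param segment_len_s segment length (default 2.5).
#' @param min_overlap minimum overlapped fraction of the gasp support
#'   (default 0.5).
#' @return Logical vector, one element per segment.
#' @export
segment_labels <- function(truth, start_s, segment_len_s = 2.5, min_overlap = 0.5) {
  stopifnot(inherits(truth, "ground_truth"))
  ev <- truth$events
  vapply(start_s, function(s) {
    e <- s + segment_len_s
    if (nrow(ev) == 0) return(FALSE)
    ov <- pmin(e, ev$onset_s + ev$duration_s) - pmax(s, ev$onset_s)
    any(ov >= min_overlap * ev$duration_s - 1e-9)
  }, logical(1))
}

#' Write scene ground truth to plain-text files
#'
#' Events go to a tab-separated file (`onset_s`, `duration_s`, `kind`);
#' per-segment labels to a CSV (`start_s`, `label`).
#'
#' @param truth a `ground_truth`.
#' @param events_path output TSV path (NULL to skip).
#' @param labels_path output CSV path (NULL to skip).
#' @param segment_len_s,hop_s segmentation grid used for the label file.
#' @return Invisibly, the label data.frame.
#' @export
write_ground_truth <- function(truth, events_path = NULL, labels_path = NULL,
                               segment_len_s = 2.5, hop_s = segment_len_s) {
  if (!is.null(events_path)) {
    utils::write.table(truth$events, events_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  k <- max(0L, floor((truth$duration_s - segment_len_s) / hop_s) + 1L)
  starts <- (seq_len(k) - 1L) * hop_s
  lab <- data.frame(start_s = starts,
                    label = as.integer(segment_labels(truth, starts, segment_len_s)))
  if (!is.null(labels_path)) {
    utils::write.csv(lab, labels_path, row.names = FALSE)
  }
  invisible(lab)
}
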