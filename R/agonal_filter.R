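# Temporal plausibility filter: per-segment positives become alarms only
# when detections recur at the physiologic agonal rate of 3-6 breaths per
# minute, i.e. successive breath onsets 10-20 s apart (inclusive at both
# boundaries). Adjacent positive segments within a short merge window are
# one breath (a gasp can straddle a segment boundary).

#' Configuration of the agonal-rate filter
#'
#' @param min_gap_s minimum inter-breath onset gap (default 10 s = 6/min).
#' @param max_gap_s maximum inter-breath onset gap (default 20 s = 3/min).
#' @param breaths_required chained breaths needed to alarm (2 or 3;
#'   default 3).
#' @param merge_window_s positives within this window of the previous
#'   positive merge into one breath event (default 5 s, i.e. two
#'   consecutive 2.5 s segments).
#' @return A `filter_config`.
#' @export
filter_config <- function(min_gap_s = 10, max_gap_s = 20,
                          breaths_required = 3, merge_window_s = 5) {
  if (!(min_gap_s > 0 && min_gap_s < max_gap_s)) stopf("need 0 < min_gap_s < max_gap_s")
  if (breaths_required < 2) stopf("breaths_required must be >= 2")
  if (merge_window_s < 0 || merge_window_s >= min_gap_s) {
    stopf("merge_window_s must be in [0, min_gap_s)")
  }
  structure(list(min_gap_s = min_gap_s, max_gap_s = max_gap_s,
                 breaths_required = as.integer(breaths_required),
                 merge_window_s = merge_window_s),
            class = "filter_config")
}

#' Initial filter state
#' @return A fresh `filter_state` (no pending breaths).
#' @export
filter_init <- function() {
  structure(list(chain = numeric(0), last_positive_s = -Inf, last_time_s = -Inf),
            class = "filter_state")
}

#' Advance the filter by one segment
#'
#' A positive segment within `merge_window_s` of the previous positive
#' extends the current breath event; otherwise it opens a new breath event
#' whose onset either chains to the previous event (onset gap within
#' `[min_gap_s, max_gap_s]`) or restarts the chain. When the chain reaches
#' `breaths_required` an alarm fires and the alarming event seeds a fresh
#' chain.
#'
#' @param state a `filter_state`.
#' @param segment_start_s segment start time; must strictly increase
#'   across calls.
#' @param positive logical, the segment's predicted label.
#' @param config a [filter_config()].
#' @return List with `state` (updated) and `alarm` (`NULL`, or a list with
#'   `time_s` and the contributing breath `onsets_s`).
#' @export
filter_step <- function(state, segment_start_s, positive, config = filter_config()) {
  stopifnot(inherits(state, "filter_state"))
  if (segment_start_s <= state$last_time_s) {
    stopf("segment start times must be strictly increasing (%.3f after %.3f)",
          segment_start_s, state$last_time_s)
  }
  state$last_time_s <- segment_start_s
  alarm <- NULL
  if (isTRUE(positive)) {
    t <- segment_start_s
    if (t - state$last_positive_s <= config$merge_window_s) {
      # same breath event; onset unchanged
      state$last_positive_s <- t
    } else {
      state$last_positive_s <- t
      n <- length(state$chain)
      if (n == 0) {
        state$chain <- t
      } else {
        gap <- t - state$chain[n]
        if (gap >= config$min_gap_s && gap <= config$max_gap_s) {
          state$chain <- c(state$chain, t)
        } else {
          state$chain <- t   # too fast or too slow: restart at this event
        }
      }
      if (length(state$chain) >= config$breaths_required) {
        alarm <- list(time_s = t, onsets_s = state$chain)
        state$chain <- t     # alarming event seeds the next chain
      }
    }
  }
  list(state = state, alarm = alarm)
}

#' Run the filter over a prediction stream
#'
#' @param predictions data.frame with `start_s` and either logical `label`
#'   or numeric `prob` (thresholded at `threshold`). Must be time-sorted.
#' @param config a [filter_config()].
#' @param threshold probability threshold when only `prob` is supplied.
#' @return An `alarm_trace`: list with `alarms` (data.frame `time_s`,
#'   `n_breaths`, `first_onset_s`), `onsets` (list of contributing breath
#'   onsets per alarm), `n_alarms` and `n_positive_segments`.
#' @export
run_stream <- function(predictions, config = filter_config(), threshold = 0.5) {
  predictions <- as.data.frame(predictions)
  lab <- if ("label" %in% names(predictions)) {
    as.logical(predictions$label)
  } else if ("prob" %in% names(predictions)) {
    predictions$prob >= threshold
  } else {
    stopf("predictions need a label or prob column")
  }
  state <- filter_init()
  times <- numeric(0); nb <- integer(0); fo <- numeric(0)
  onsets <- list()
  for (i in seq_len(nrow(predictions))) {
    res <- filter_step(state, predictions$start_s[i], lab[i], config)
    state <- res$state
    if (!is.null(res$alarm)) {
      times <- c(times, res$alarm$time_s)
      nb <- c(nb, length(res$alarm$onsets_s))
      fo <- c(fo, res$alarm$onsets_s[1])
      onsets[[length(onsets) + 1L]] <- res$alarm$onsets_s
    }
  }
  structure(
    list(alarms = data.frame(time_s = times, n_breaths = nb, first_onset_s = fo),
         onsets = onsets, n_alarms = length(times),
         n_positive_segments = sum(lab)),
    class = "alarm_trace"
  )
}

#' @export
print.alarm_trace <- function(x, ...) {
  cat(sprintf("<alarm_trace: %d alarms from %d positive segments>\n",
              x$n_alarms, x$n_positive_segments))
  invisible(x)
}
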