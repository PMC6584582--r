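# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# A small trained pipeline (corpus + featurizer + detector) used by the
# cancellation, pipeline and benchmark tests. 30 scenes/class keeps the
# build under a minute; 128 PCA components fit comfortably in the ~320
# training segments.
fixture_pipeline <- function() {
  if (!is.null(.fixture_cache$pipeline)) return(.fixture_cache$pipeline)
  corpus <- make_training_corpus(30, seed = 42)
  featurizer <- fit_featurizer(corpus$logmel, 128)
  detector <- train_detector(embed_segments(corpus$logmel, featurizer),
                             corpus$labels, seed = 7)
  .fixture_cache$pipeline <- list(corpus = corpus, featurizer = featurizer,
                                  detector = detector)
  .fixture_cache$pipeline
}

# Two well-separated Gaussian blobs in 2-D; the detector unit-test fixture.
fixture_blobs <- function(n = 200, sep = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n, 0), n, 2), matrix(rnorm(2 * n, sep), n, 2))
  list(X = X, y = c(rep(FALSE, n), rep(TRUE, n)))
}

fixture_blob_model <- function() {
  if (!is.null(.fixture_cache$blob_model)) return(.fixture_cache$blob_model)
  b <- fixture_blobs()
  .fixture_cache$blob_model <- list(
    model = train_detector(b$X, b$y, C = 10, seed = 1), X = b$X, y = b$y)
  .fixture_cache$blob_model
}

# Independent reference implementation of the agonal-rate state machine,
# written as a direct transcription of the chaining rules; used as the
# oracle for the streaming filter.
reference_alarms <- function(start_s, label, min_gap = 10, max_gap = 20,
                             breaths = 3, merge = 5) {
  # collapse merged positives into breath-event onsets
  pos <- start_s[label]
  events <- numeric(0)
  last_pos <- -Inf
  for (t in pos) {
    if (t - last_pos > merge) events <- c(events, t)
    last_pos <- t
  }
  alarms <- numeric(0)
  chain <- numeric(0)
  for (e in events) {
    if (length(chain) == 0) {
      chain <- e
    } else {
      gap <- e - chain[length(chain)]
      chain <- if (gap >= min_gap && gap <= max_gap) c(chain, e) else e
    }
    if (length(chain) >= breaths) {
      alarms <- c(alarms, e)
      chain <- e
    }
  }
  alarms
}
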