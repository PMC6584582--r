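# Segment featurization: Hann-windowed STFT, triangular mel filterbank with
# log compression, and a PCA projection to a 256-dimensional embedding.
# The mel/STFT defaults (25 ms window, 10 ms hop, 64 mel bands, 125-7500 Hz,
# log offset 0.01) follow the convention of widely used audio-event
# feature extractors; every one of them is exposed in mel_params().

#' STFT / mel filterbank parameters
#'
#' @param win_s analysis window length in seconds (default 25 ms).
#' @param hop_s hop between frames in seconds (default 10 ms).
#' @param n_fft FFT size (>= window length in samples).
#' @param n_mels number of mel bands (default 64).
#' @param fmin_hz,fmax_hz filterbank edge frequencies.
#' @param log_offset additive offset inside the log (keeps entries finite).
#' @return A named list of parameters.
#' @export
mel_params <- function(win_s = 0.025, hop_s = 0.010, n_fft = 512,
                       n_mels = 64, fmin_hz = 125, fmax_hz = 7500,
                       log_offset = 0.01) {
  list(win_s = win_s, hop_s = hop_s, n_fft = as.integer(n_fft),
       n_mels = as.integer(n_mels), fmin_hz = fmin_hz, fmax_hz = fmax_hz,
       log_offset = log_offset)
}

#' Short-time Fourier transform
#'
#' Hann-windowed (periodic window) STFT. The frame count is
#' `1 + floor((N - win)/hop)`; each frame is zero-padded to `n_fft` and the
#' non-negative-frequency half of the DFT is returned.
#'
#' @param x numeric samples or an [audio_clip()].
#' @param sample_rate_hz sampling rate (taken from the clip if given one).
#' @param win_s,hop_s,n_fft framing parameters, see [mel_params()].
#' @return Complex matrix, `n_fft/2 + 1` frequency bins (rows) by frames
#'   (columns); attributes `sample_rate_hz`, `hop_s`.
#' @export
stft <- function(x, sample_rate_hz = 16000, win_s = 0.025, hop_s = 0.010,
                 n_fft = 512) {
  if (inherits(x, "audio_clip")) {
    sample_rate_hz <- x$sample_rate_hz
    x <- x$samples
  }
  fs <- sample_rate_hz
  win <- round(win_s * fs)
  hop <- round(hop_s * fs)
  if (win > length(x)) stopf("window (%d samples) longer than signal (%d)", win, length(x))
  if (n_fft < win) stopf("n_fft must be >= window length in samples")
  n_frames <- 1L + (length(x) - win) %/% hop
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1) / win)
  frames <- matrix(0, nrow = n_fft, ncol = n_frames)
  idx0 <- (seq_len(n_frames) - 1L) * hop
  for (j in seq_len(n_frames)) {
    frames[seq_len(win), j] <- x[(idx0[j] + 1L):(idx0[j] + win)] * w
  }
  S <- stats::mvfft(frames)[seq_len(n_fft %/% 2 + 1L), , drop = FALSE]
  attr(S, "sample_rate_hz") <- fs
  attr(S, "hop_s") <- hop_s
  S
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank matrix
#'
#' @param n_mels number of bands (>= 2).
#' @param n_fft FFT size.
#' @param sample_rate_hz sampling rate.
#' @param fmin_hz,fmax_hz band edges; `fmax_hz` must not exceed Nyquist.
#' @return Matrix `n_mels` by `n_fft/2 + 1`; each row a triangular filter
#'   with compact support.
#' @export
mel_filterbank <- function(n_mels = 64, n_fft = 512, sample_rate_hz = 16000,
                           fmin_hz = 125, fmax_hz = 7500) {
  if (n_mels < 2) stopf("n_mels must be >= 2")
  if (!(fmin_hz < fmax_hz)) stopf("fmin_hz must be < fmax_hz")
  if (fmax_hz > sample_rate_hz / 2) stopf("fmax_hz exceeds Nyquist")
  n_bins <- n_fft %/% 2 + 1L
  bin_hz <- (seq_len(n_bins) - 1) * sample_rate_hz / n_fft
  pts <- mel_to_hz(seq(hz_to_mel(fmin_hz), hz_to_mel(fmax_hz), length.out = n_mels + 2))
  fb <- matrix(0, n_mels, n_bins)
  for (i in seq_len(n_mels)) {
    lo <- pts[i]; ce <- pts[i + 1]; hi <- pts[i + 2]
    up <- (bin_hz - lo) / (ce - lo)
    dn <- (hi - bin_hz) / (hi - ce)
    fb[i, ] <- pmax(0, pmin(up, dn))
  }
  attr(fb, "center_hz") <- pts[2:(n_mels + 1)]
  fb
}

#' Log-mel spectrogram
#'
#' Applies a triangular mel filterbank to the STFT power spectrum and
#' log-compresses: `log(mel_power + log_offset)`. Entries are always
#' finite.
#'
#' @param S complex STFT matrix from [stft()], or an [audio_clip()] /
#'   numeric vector (in which case the STFT is computed first).
#' @param params parameters from [mel_params()].
#' @param sample_rate_hz sampling rate (required when `S` is a bare
#'   matrix without attributes).
#' @return Matrix `n_mels` by frames of log-energies; attribute
#'   `frame_hop_s`.
#' @export
log_mel <- function(S, params = mel_params(), sample_rate_hz = 16000) {
  if (!is.matrix(S)) {
    S <- stft(S, sample_rate_hz, params$win_s, params$hop_s, params$n_fft)
  }
  fs <- attr(S, "sample_rate_hz") %||% sample_rate_hz
  fb <- mel_filterbank(params$n_mels, params$n_fft, fs, params$fmin_hz, params$fmax_hz)
  out <- log(fb %*% (Mod(S)^2) + params$log_offset)
  attr(out, "frame_hop_s") <- params$hop_s
  out
}

# Flattened log-mel features for every segment of a stream: n_segments x d.
# Each segment is peak-normalized to [-1, 1] first, so the embedding sees
# spectral shape rather than recording level (distance invariance).
logmel_matrix <- function(stream, params = mel_params()) {
  k <- n_segments(stream)
  X <- NULL
  for (i in seq_len(k)) {
    x <- stream$samples[i, ]
    pk <- max(abs(x))
    if (pk > 0) x <- x / pk
    r <- as.numeric(log_mel(x, params, stream$sample_rate_hz))
    if (is.null(X)) X <- matrix(0, k, length(r))
    X[i, ] <- r
  }
  X
}

#' Principal component analysis by the smaller Gram matrix
#'
#' Exact PCA via an eigendecomposition of whichever of `X'X` or `XX'` is
#' smaller, so fitting 256 components to a few hundred very long flattened
#' spectrograms stays cheap. Component signs are fixed so the entry of
#' largest magnitude in each component is positive.
#'
#' @param X data matrix, observations in rows.
#' @param k number of components (<= min(dim(X))).
#' @return List with `mean`, `components` (k x ncol(X), orthonormal rows,
#'   sorted by decreasing variance) and `explained_variance`.
#' @export
fit_pca <- function(X, k) {
  n <- nrow(X); d <- ncol(X)
  if (k > min(n, d)) stopf("k = %d exceeds min(n, d) = %d", k, min(n, d))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (n <= d) {
    G <- tcrossprod(Xc)             # n x n
    e <- eigen(G, symmetric = TRUE)
    ev <- pmax(e$values[seq_len(k)], 0)
    V <- crossprod(Xc, e$vectors[, seq_len(k), drop = FALSE])
    V <- sweep(V, 2, sqrt(pmax(ev, 1e-300)), "/")
  } else {
    G <- crossprod(Xc)              # d x d
    e <- eigen(G, symmetric = TRUE)
    ev <- pmax(e$values[seq_len(k)], 0)
    V <- e$vectors[, seq_len(k), drop = FALSE]
  }
  # deterministic sign convention
  for (j in seq_len(k)) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  list(mean = mu, components = t(V), explained_variance = ev / (n - 1))
}

#' Fit the featurizer (mel front end + PCA) on training segments
#'
#' PCA is fitted on the flattened log-mel matrices of the training segments
#' only; in cross-validation it must be refit per fold on that fold's
#' training split so validation data never leaks into the embedding basis.
#'
#' @param stream a `segment_stream` of training segments, or a numeric
#'   matrix of precomputed flattened log-mel rows.
#' @param n_components embedding dimension (default 256).
#' @param params [mel_params()].
#' @param sample_rate_hz sampling rate when `stream` is a bare matrix.
#' @return A `featurizer_model`.
#' @export
fit_featurizer <- function(stream, n_components = 256, params = mel_params(),
                           sample_rate_hz = 16000) {
  X <- if (is.matrix(stream)) stream else logmel_matrix(stream, params)
  if (nrow(X) < n_components) {
    stopf("need at least %d training segments, got %d", n_components, nrow(X))
  }
  pca <- fit_pca(X, n_components)
  structure(
    list(params = params, n_components = as.integer(n_components),
         pca_mean = pca$mean, pca_components = pca$components,
         explained_variance = pca$explained_variance,
         sample_rate_hz = if (is.matrix(stream)) sample_rate_hz else stream$sample_rate_hz,
         fitted = TRUE),
    class = "featurizer_model"
  )
}

#' @export
print.featurizer_model <- function(x, ...) {
  cat(sprintf("<featurizer_model: %d mel bands -> %d PCA components, %.1f%% variance>\n",
              x$params$n_mels, x$n_components,
              100 * sum(x$explained_variance) / max(sum(x$explained_variance), 1e-300)))
  invisible(x)
}

#' Embed segments with a fitted featurizer
#'
#' Flattened log-mel, centered on the training mean, projected onto the PCA
#' components. Deterministic.
#'
#' @param x a `segment_stream`, an [audio_clip()] holding exactly one
#'   segment, or a precomputed flattened log-mel matrix.
#' @param model a fitted `featurizer_model`.
#' @return Embedding matrix, one row per segment, `n_components` columns.
#' @export
embed_segments <- function(x, model) {
  if (!inherits(model, "featurizer_model") || !isTRUE(model$fitted)) {
    stopf("featurizer model is not fitted")
  }
  X <- if (is.matrix(x) && !inherits(x, "audio_clip")) {
    x
  } else if (inherits(x, "segment_stream")) {
    logmel_matrix(x, model$params)
  } else if (inherits(x, "audio_clip")) {
    matrix(as.numeric(log_mel(peak_normalize(x)$samples, model$params,
                              x$sample_rate_hz)), nrow = 1)
  } else {
    stopf("x must be a segment_stream, audio_clip or log-mel matrix")
  }
  if (ncol(X) != length(model$pca_mean)) {
    stopf("log-mel dimension %d does not match the fitted model (%d)",
          ncol(X), length(model$pca_mean))
  }
  sweep(X, 2, model$pca_mean) %*% t(model$pca_components)
}

#' Reconstruct flattened log-mels from embeddings
#'
#' Back-projection onto the mel feature space; used to measure
#' reconstruction error of the PCA basis.
#'
#' @param E embedding matrix from [embed_segments()].
#' @param model the fitted `featurizer_model`.
#' @return Matrix of reconstructed flattened log-mel rows.
#' @export
reconstruct_segments <- function(E, model) {
  sweep(E %*% model$pca_components, 2, model$pca_mean, "+")
}
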