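test_that("the STFT matches a brute-force DFT and the framing contract", {
  set.seed(3)
  x <- rnorm(1600)  # 0.1 s at 16 kHz
  S <- stft(x, 16000)
  win <- 400; hop <- 160; n_fft <- 512
  expect_equal(ncol(S), 1 + floor((1600 - win) / hop))
  expect_equal(nrow(S), n_fft / 2 + 1)
  # O(N^2) DFT oracle on every frame
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1)) / win)
  for (j in seq_len(ncol(S))) {
    fr <- x[((j - 1) * hop + 1):((j - 1) * hop + win)] * w
    ref <- vapply(0:(n_fft / 2), function(k) {
      sum(fr * exp(-2i * pi * k * (0:(win - 1)) / n_fft))
    }, complex(1))
    expect_lt(max(Mod(S[, j] - ref)), 1e-9)
  }
})

test_that("STFT handles tones, silence and bad windows", {
  t <- (0:39999) / 16000
  S <- stft(sin(2 * pi * 1000 * t), 16000)
  bins <- apply(Mod(S), 2, which.max) - 1
  expect_true(all(bins == round(1000 / (16000 / 512))))
  expect_true(all(Mod(stft(numeric(8000), 16000)) == 0))
  expect_error(stft(rnorm(100), 16000), "window")
})

test_that("the mel filterbank is triangular, compactly supported and peaks at centers", {
  fb <- mel_filterbank()
  expect_equal(dim(fb), c(64, 257))
  expect_true(all(rowSums(fb) > 0))
  # compact support: each row is one contiguous block of non-zeros
  for (i in c(1, 16, 32, 64)) {
    nz <- which(fb[i, ] > 0)
    expect_lt(length(nz), 257)
    expect_equal(nz, seq(min(nz), max(nz)))
  }
  # a tone at a band's center frequency maximizes that band
  centers <- attr(fb, "center_hz")
  for (band in c(10, 30, 50)) {
    tone <- sin(2 * pi * centers[band] * (0:39999) / 16000)
    lm <- log_mel(tone, sample_rate_hz = 16000)
    expect_equal(unname(which.max(rowMeans(lm))), band)
  }
  expect_error(mel_filterbank(n_mels = 1), "n_mels")
  expect_error(mel_filterbank(fmax_hz = 9000), "Nyquist")
  expect_error(mel_filterbank(fmin_hz = 8000, fmax_hz = 7000), "fmin")
})

test_that("log-mel output is finite and smooth for white noise", {
  expect_true(all(is.finite(log_mel(numeric(40000), sample_rate_hz = 16000))))
  # Monte-Carlo oracle: adjacent-band log-energy steps stay bounded
  deltas <- vapply(1:50, function(s) {
    set.seed(s)
    lm <- rowMeans(log_mel(rnorm(16000), sample_rate_hz = 16000))
    mean(abs(diff(lm)))
  }, numeric(1))
  expect_lt(mean(deltas), 1.0)
})

test_that("PCA recovers a planted low-rank subspace", {
  set.seed(8)
  basis <- qr.Q(qr(matrix(rnorm(50 * 3), 50, 3)))
  X <- matrix(rnorm(400 * 3), 400, 3) %*% t(basis) * 5 +
    matrix(rnorm(400 * 50, sd = 0.01), 400, 50)
  p <- fit_pca(X, 10)
  expect_gt(sum(p$explained_variance[1:3]) / sum(p$explained_variance), 0.99)
  expect_false(is.unsorted(rev(p$explained_variance)))
  # eigen-decomposition oracle on the covariance matrix
  ev_ref <- eigen(stats::cov(X), symmetric = TRUE)$values[1:10]
  expect_equal(p$explained_variance, ev_ref, tolerance = 1e-8)
  # deterministic refit
  expect_identical(p$components, fit_pca(X, 10)$components)
  expect_error(fit_pca(X, 60), "exceeds")
})

test_that("the featurizer embeds with an orthonormal basis of the stated dimension", {
  set.seed(9)
  segs <- matrix(rnorm(80 * 8000, sd = 0.1), 80)
  stream <- structure(list(samples = segs, start_s = (0:79) * 0.5,
                           segment_len_s = 0.5, hop_s = 0.5,
                           sample_rate_hz = 16000L),
                      class = "segment_stream")
  fm <- fit_featurizer(stream, 32)
  expect_equal(nrow(fm$pca_components), 32)
  expect_lt(max(abs(tcrossprod(fm$pca_components) - diag(32))), 1e-6)
  expect_error(fit_featurizer(stream, 100), "at least")

  E <- embed_segments(stream, fm)
  expect_equal(dim(E), c(80, 32))
  # the training mean embeds to the origin
  expect_lt(max(abs(embed_segments(matrix(fm$pca_mean, 1), fm))), 1e-9)
  # identical segments give identical embeddings (to BLAS summation order)
  one <- structure(list(samples = stream$samples[1, , drop = FALSE],
                        start_s = 0, segment_len_s = 0.5, hop_s = 0.5,
                        sample_rate_hz = 16000L), class = "segment_stream")
  expect_equal(E[1, ], embed_segments(one, fm)[1, ], tolerance = 1e-12)

  unfitted <- fm; unfitted$fitted <- FALSE
  expect_error(embed_segments(E, unfitted), "not fitted")
})

test_that("more components reconstruct better, and projection is a contraction", {
  set.seed(10)
  X <- matrix(rnorm(120 * 8000, sd = 0.1), 120)
  train <- X[1:100, ]; hold <- X[101:120, , drop = FALSE]
  lm_train <- agonalert:::logmel_matrix(
    structure(list(samples = train, start_s = (0:99) * 0.5, segment_len_s = 0.5,
                   hop_s = 0.5, sample_rate_hz = 16000L), class = "segment_stream"))
  lm_hold <- agonalert:::logmel_matrix(
    structure(list(samples = hold, start_s = (0:19) * 0.5, segment_len_s = 0.5,
                   hop_s = 0.5, sample_rate_hz = 16000L), class = "segment_stream"))
  err <- vapply(c(16, 64), function(k) {
    fm <- fit_featurizer(lm_train, k, sample_rate_hz = 16000)
    R <- reconstruct_segments(embed_segments(lm_hold, fm), fm)
    mean((R - lm_hold)^2)
  }, numeric(1))
  expect_lte(err[2], err[1])
  # contraction: reconstruction MSE bounded by held-out variance about the
  # training mean
  fm <- fit_featurizer(lm_train, 64, sample_rate_hz = 16000)
  R <- reconstruct_segments(embed_segments(lm_hold, fm), fm)
  expect_lte(mean((R - lm_hold)^2),
             mean(sweep(lm_hold, 2, fm$pca_mean)^2))
})
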