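# Segment classifier: an RBF-kernel SVM with C = 10 and Platt-calibrated
# probabilities, a random-Fourier-feature approximation for cheap streaming
# inference, and a grouped k-fold cross-validation harness that never lets
# a source recording (or any augmented variant of it) straddle the
# train/validation split.

#' Train the RBF-SVM segment detector
#'
#' @param embeddings numeric matrix, one row per segment (256 columns with
#'   the default featurizer).
#' @param labels logical or 0/1 vector; `TRUE`/1 = agonal.
#' @param C regularization parameter (default 10).
#' @param gamma RBF width; default `1/(ncol(embeddings) * var(embeddings))`
#'   (the "scale" heuristic).
#' @param seed integer seed (the probability calibration uses internal
#'   cross-validation).
#' @param threshold probability operating point for [predict_detector()]
#'   (default 0.5).
#' @return A `detector_model`.
#' @export
train_detector <- function(embeddings, labels, C = 10, gamma = NULL,
                           seed = 1, threshold = 0.5) {
  embeddings <- as.matrix(embeddings)
  y <- as.logical(labels)
  if (any(is.na(y))) stopf("labels must be logical or 0/1")
  if (length(unique(y)) < 2) stopf("training data must contain both classes")
  if (nrow(embeddings) != length(y)) stopf("embeddings and labels disagree in length")
  if (is.null(gamma)) gamma <- 1 / (ncol(embeddings) * stats::var(as.numeric(embeddings)))
  yf <- factor(ifelse(y, "agonal", "negative"), levels = c("negative", "agonal"))
  fit <- with_seed(seed, e1071::svm(
    x = embeddings, y = yf, kernel = "radial", cost = C, gamma = gamma,
    probability = TRUE, scale = FALSE
  ))
  model <- structure(
    list(fit = fit, C = C, gamma = gamma, dim = ncol(embeddings),
         threshold = threshold, seed = seed,
         train_x = embeddings, train_y = y),
    class = "detector_model"
  )
  # orient decision values so positive score = agonal
  dec <- raw_decision(model, embeddings[c(which(y)[1], which(!y)[1]), , drop = FALSE])
  model$dec_sign <- if (dec[1] >= dec[2]) 1 else -1
  model
}

#' @export
print.detector_model <- function(x, ...) {
  cat(sprintf("<detector_model: RBF-SVM, C = %g, gamma = %.4g, %d SVs, threshold %.2f>\n",
              x$C, x$gamma, nrow(x$fit$SV), x$threshold))
  invisible(x)
}

raw_decision <- function(model, X) {
  p <- stats::predict(model$fit, X, decision.values = TRUE)
  as.numeric(attr(p, "decision.values"))
}

#' SVM decision values, oriented so positive means agonal
#'
#' Equals the kernel expansion `sum_i alpha_i k(x, sv_i) + b` over the
#' support vectors.
#'
#' @param model a `detector_model`.
#' @param X embedding matrix.
#' @return Numeric vector of decision values.
#' @export
decision_values <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$dim) stopf("embedding dimension %d != model dimension %d", ncol(X), model$dim)
  model$dec_sign * raw_decision(model, X)
}

#' Classify segments with a fitted detector
#'
#' @param model a `detector_model`.
#' @param X embedding matrix (rows = segments).
#' @param threshold probability threshold; defaults to the model's
#'   operating point. `label = probability >= threshold`.
#' @return data.frame with `prob` (calibrated probability of agonal) and
#'   `label` (logical).
#' @export
predict_detector <- function(model, X, threshold = model$threshold) {
  X <- as.matrix(X)
  if (ncol(X) != model$dim) stopf("embedding dimension %d != model dimension %d", ncol(X), model$dim)
  p <- stats::predict(model$fit, X, probability = TRUE)
  prob <- attr(p, "probabilities")[, "agonal"]
  data.frame(prob = as.numeric(prob), label = as.numeric(prob) >= threshold)
}

#' Random-Fourier-feature approximation of the detector
#'
#' Monte-Carlo approximation of the RBF kernel: `D` cosine features with
#' Gaussian projections `omega ~ N(0, 2 gamma I)` and uniform phases, so
#' `(2/D) sum_i cos(w_i'x + b_i) cos(w_i'y + b_i) -> exp(-gamma ||x-y||^2)`
#' as `D` grows. The linear weights are mapped from the exact model's dual
#' coefficients, `w = sum_i alpha_i z(sv_i)` with bias `-rho`, so the
#' linear score converges to the exact decision function everywhere
#' (including far from the training data) and per-segment cost drops to a
#' single `D`-dimensional dot product.
#'
#' @param model a fitted `detector_model`.
#' @param D number of Monte-Carlo features (>= 64).
#' @param seed integer seed for the projections; the result is
#'   deterministic given the seed.
#' @return An `rff_model`.
#' @export
approximate_detector <- function(model, D = 1024, seed = 1) {
  stopifnot(inherits(model, "detector_model"))
  if (!is_count(D) || D < 64) stopf("D must be an integer >= 64")
  d <- model$dim
  with_seed(seed, {
    omega <- matrix(stats::rnorm(D * d, sd = sqrt(2 * model$gamma)), D, d)
    phases <- stats::runif(D, 0, 2 * pi)
  })
  Zsv <- rff_features(model$fit$SV, omega, phases)
  w <- as.numeric(crossprod(Zsv, model$fit$coefs)) * model$dec_sign
  b <- -model$fit$rho * model$dec_sign
  structure(
    list(omega = omega, phases = phases, weights = w, bias = b,
         D = as.integer(D), seed = as.integer(seed), gamma = model$gamma,
         dim = d),
    class = "rff_model"
  )
}

rff_features <- function(X, omega, phases) {
  X <- as.matrix(X)
  sqrt(2 / nrow(omega)) * cos(sweep(X %*% t(omega), 2, phases, "+"))
}

#' Approximate kernel value from an RFF model
#'
#' @param rff an `rff_model`.
#' @param x,y embedding vectors.
#' @return The Monte-Carlo kernel estimate `k_hat(x, y)`.
#' @export
rff_kernel <- function(rff, x, y) {
  zx <- as.numeric(rff_features(matrix(x, 1), rff$omega, rff$phases))
  zy <- as.numeric(rff_features(matrix(y, 1), rff$omega, rff$phases))
  sum(zx * zy)
}

#' Score segments with the RFF approximation
#'
#' @param rff an `rff_model`.
#' @param X embedding matrix.
#' @return data.frame with `score` (signed linear score) and `label`
#'   (`score >= 0`).
#' @export
predict_rff <- function(rff, X) {
  X <- as.matrix(X)
  if (ncol(X) != rff$dim) stopf("embedding dimension mismatch")
  s <- as.numeric(rff_features(X, rff$omega, rff$phases) %*% rff$weights + rff$bias)
  data.frame(score = s, label = s >= 0)
}

#' Grouped fold assignment
#'
#' Assigns source recordings to `k` folds so that no source (and therefore
#' none of its augmented variants, which share its `source_id`) appears in
#' both the training and validation side of any fold. Assignment is
#' stratified by source class and shuffled by `seed`.
#'
#' @param source_id character vector, one entry per segment.
#' @param source_class logical vector, one entry per segment (`TRUE` if
#'   the source contains agonal events).
#' @param k number of folds (default 10).
#' @param seed integer shuffle seed.
#' @return Named integer vector: fold index per unique source id.
#' @export
plan_folds <- function(source_id, source_class, k = 10, seed = 1) {
  src <- !duplicated(source_id)
  ids <- source_id[src]
  cls <- source_class[src]
  for (cl in unique(cls)) {
    if (sum(cls == cl) < k) {
      stopf("grouping infeasible: class %s has %d sources but k = %d",
            cl, sum(cls == cl), k)
    }
  }
  fold <- integer(length(ids))
  names(fold) <- ids
  with_seed(seed, {
    for (cl in unique(cls)) {
      members <- sample(ids[cls == cl])
      fold[members] <- rep_len(seq_len(k), length(members))
    }
  })
  fold
}

# Youden-J-optimal probability cut. When several thresholds tie (the
# classes separate on the training data), the midpoint of the empty score
# gap is used so the operating point transfers to held-out data.
youden_threshold <- function(prob, y) {
  th <- sort(unique(prob))
  j <- vapply(th, function(t) {
    sens <- mean(prob[y] >= t)
    spec <- mean(prob[!y] < t)
    sens + spec - 1
  }, numeric(1))
  best <- th[which.max(j)]
  below <- prob[prob < best]
  if (length(below)) (best + max(below)) / 2 else best
}

#' Grouped k-fold cross-validation of the full pipeline
#'
#' For each fold the featurizer (PCA basis) is refit on the training
#' segments only, the SVM is trained on the resulting embeddings, and the
#' held-out sources are scored. The mel front end is a fixed, data-free
#' transform, so log-mel features are computed once for all segments. The
#' operating threshold of each fold is chosen on its training
#' probabilities by maximizing Youden's J.
#'
#' @param corpus an `agonal_corpus` from [make_training_corpus()] (or any
#'   list with `logmel`, `labels`, `source_id`).
#' @param k number of folds (default 10).
#' @param seed integer seed (fold shuffle, SVM calibration).
#' @param n_components PCA embedding dimension (default 256).
#' @param C,gamma SVM hyperparameters, see [train_detector()].
#' @return List with per-fold AUCs, pooled ROC/AUC, pooled sensitivity and
#'   specificity with 95 per cent Wald intervals, the fold plan, and the
#'   pooled validation scores.
#' @export
crossvalidate <- function(corpus, k = 10, seed = 1, n_components = 256,
                          C = 10, gamma = NULL) {
  X <- corpus$logmel
  y <- as.logical(corpus$labels)
  sid <- corpus$source_id
  src_class <- stats::ave(y, sid, FUN = any)
  fold_of_source <- plan_folds(sid, src_class, k, seed)
  fold <- fold_of_source[sid]
  pooled_prob <- numeric(length(y))
  pooled_pred <- logical(length(y))
  fold_auc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(intersect(sid[tr], sid[!tr])) > 0) {
      stopf("internal error: fold %d leaks sources", f)  # FoldPlan invariant
    }
    featurizer <- fit_featurizer(X[tr, , drop = FALSE], n_components,
                                 sample_rate_hz = corpus$sample_rate_hz)
    Etr <- embed_segments(X[tr, , drop = FALSE], featurizer)
    Eva <- embed_segments(X[!tr, , drop = FALSE], featurizer)
    det <- train_detector(Etr, y[tr], C = C, gamma = gamma,
                          seed = derive_seed(seed, f))
    ptr <- predict_detector(det, Etr)$prob
    th <- youden_threshold(ptr, y[tr])
    pva <- predict_detector(det, Eva)$prob
    pooled_prob[!tr] <- pva
    pooled_pred[!tr] <- pva >= th
    fold_auc[f] <- roc_auc(pva, y[!tr])$auc
  }
  pooled <- roc_auc(pooled_prob, y)
  tp <- sum(pooled_pred & y); fn <- sum(!pooled_pred & y)
  tn <- sum(!pooled_pred & !y); fp <- sum(pooled_pred & !y)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  list(
    fold_auc = fold_auc, mean_auc = mean(fold_auc),
    pooled_auc = pooled$auc, roc = pooled$roc,
    sensitivity = sens, sensitivity_ci = wald_ci(sens, tp + fn),
    specificity = spec, specificity_ci = wald_ci(spec, tn + fp),
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
    fold_of_source = fold_of_source, fold = fold,
    prob = pooled_prob, pred = pooled_pred, labels = y
  )
}
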