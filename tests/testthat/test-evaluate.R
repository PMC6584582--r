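test_that("ROC/AUC matches the Mann-Whitney statistic exactly", {
  # brute-force pairwise oracle on 50 random small instances
  for (s in 1:50) {
    set.seed(s)
    n1 <- sample(3:12, 1); n0 <- sample(3:12, 1)
    y <- c(rep(TRUE, n1), rep(FALSE, n0))
    sc <- round(rnorm(n1 + n0), 1)  # ties on purpose
    u <- 0
    for (i in which(y)) for (j in which(!y)) {
      u <- u + (sc[i] > sc[j]) + 0.5 * (sc[i] == sc[j])
    }
    expect_equal(roc_auc(sc, y)$auc, u / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("AUC behaves at the extremes and under monotone transforms", {
  y <- c(rep(FALSE, 50), rep(TRUE, 50))
  sc <- c(rnorm(50, 0, 0.1), rnorm(50, 10, 0.1))
  expect_equal(roc_auc(sc, y)$auc, 1.0)
  # independent scores: AUC ~ 0.5
  set.seed(42)
  y2 <- runif(10000) < 0.5
  sc2 <- rnorm(10000)
  expect_equal(roc_auc(sc2, y2)$auc, 0.5, tolerance = 0.02)
  # invariance under a strictly monotone transform
  expect_equal(roc_auc(exp(sc2 / 3), y2)$auc, roc_auc(sc2, y2)$auc,
               tolerance = 1e-12)
  # ROC is monotone non-decreasing
  r <- roc_auc(sc2, y2)$roc
  expect_false(is.unsorted(r$fpr))
  expect_false(is.unsorted(r$tpr))
  expect_error(roc_auc(sc2, rep(TRUE, 10000)), "both classes")
})

test_that("Wald intervals reproduce the published operating points", {
  ci <- wald_ci(0.9724, 7316)
  expect_equal(round_half_up(100 * ci[1], 2), 96.86)
  ci2 <- wald_ci(0.9951, 7305)
  expect_equal(round_half_up(100 * ci2, 2), c(99.35, 99.67))
  ci3 <- wald_ci(0.9717, 7316)
  expect_equal(round_half_up(100 * ci3[1], 2), 96.79)
  expect_identical(wald_ci(1, 500), c(1, 1))
  expect_identical(wald_ci(0, 500), c(0, 0))
  expect_error(wald_ci(0.5, 0), "n must")
  expect_error(wald_ci(1.2, 10), "p_hat")
})

test_that("streaming false-positive rates reproduce the published arithmetic", {
  expect_equal(fp_rate(170, 117985), 0.14409)
  expect_equal(fp_rate(515, 236666), 0.21761)
  expect_equal(fp_rate(1, 117985), 0.00085)
  expect_equal(fp_rate(0, 117985), 0)
  # stream form agrees with the count form
  truth <- rep(FALSE, 2000)
  pred <- rep(FALSE, 2000); pred[1:3] <- TRUE
  expect_equal(fp_rate(pred, truth), fp_rate(3, 2000))
  expect_error(fp_rate(logical(0), logical(0)), "negative segments")
  expect_error(fp_rate(c(TRUE, FALSE), c(TRUE)), "equal length")
})

test_that("the pipeline is silent on silence and deterministic end to end", {
  fx <- fixture_pipeline()
  silent <- render_scene(scene_spec(300, events = empty_events(),
                                    noise_floor_dbfs = -55, seed = 9))
  out <- run_pipeline(silent$clip, fx$featurizer, fx$detector,
                      truth = silent$truth)
  expect_equal(out$alarms$n_alarms, 0)
  expect_equal(nrow(out$predictions), 120)
  expect_true(all(c("TP", "FP", "TN", "FN") %in% names(out$report$confusion)))
  out2 <- run_pipeline(silent$clip, fx$featurizer, fx$detector,
                       truth = silent$truth)
  expect_identical(out$predictions, out2$predictions)
})

test_that("a regular gasp train alarms by the third gasp", {
  fx <- fixture_pipeline()
  gasps <- c(0.7, 13.2, 26.2, 38.3, 50.4)  # each inside one 2.5 s segment
  sc <- render_scene(scene_spec(60, events = gasp_events(gasps, 1.0, 0.65),
                                noise_floor_dbfs = -50, seed = 51))
  out <- run_pipeline(sc$clip, fx$featurizer, fx$detector,
                      filter_config(breaths_required = 3), truth = sc$truth)
  expect_gte(out$alarms$n_alarms, 1)
  expect_lte(out$alarms$alarms$time_s[1], gasps[3] + 2.5)
  expect_gt(out$report$sensitivity, 0.5)
})

test_that("pipeline audio can arrive as a WAV file at telephone rate", {
  fx <- fixture_pipeline()
  sc <- render_scene(scene_spec(20, events = gasp_events(c(2, 14), 1.0, 0.65),
                                noise_floor_dbfs = -50, seed = 52))
  tel <- resample_audio(sc$clip, 8000)   # telephone-grade input
  f <- withr::local_tempfile(fileext = ".wav")
  write_wav(tel, f)
  out <- run_pipeline(f, fx$featurizer, fx$detector)
  expect_equal(nrow(out$predictions), 8)
  expect_true(any(out$predictions$label))
})

test_that("the benchmark grid degrades with distance and handles empties", {
  fx <- fixture_pipeline()
  empty <- benchmark_matrix(fx$featurizer, fx$detector,
                            data.frame(distance_m = numeric(0),
                                       interference = character(0)))
  expect_equal(nrow(empty), 0)
  grid <- benchmark_matrix(fx$featurizer, fx$detector,
                           data.frame(distance_m = c(1, 6), interference = "none"),
                           n_scenes = 4, seed = 3, scene_duration_s = 30)
  expect_equal(nrow(grid), 2)
  expect_true(all(grid$accuracy_mean >= 0 & grid$accuracy_mean <= 1))
  expect_gte(grid$accuracy_mean[grid$distance_m == 1],
             grid$accuracy_mean[grid$distance_m == 6] - 0.05)
})
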