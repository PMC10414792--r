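test_that("default base configurations cover all four encoders", {
  cfgs <- default_base_configs(epochs = 7L, seed = 3L)
  expect_named(cfgs, ENCODER_IDS)
  for (e in ENCODER_IDS) {
    expect_s3_class(cfgs[[e]], "cnn_config")
    expect_equal(cfgs[[e]]$encoder, e)
    expect_equal(cfgs[[e]]$epochs, 7L)
    expect_equal(cfgs[[e]]$seed, 3L)
  }
  # the dipeptide encoder pools locally, the positional encoders globally
  expect_equal(cfgs$ggap$pool_size, 4L)
  expect_null(cfgs$onehot$pool_size)
  expect_null(cfgs$word2vec$pool_size)
})

test_that("every meta-learner reproduces the shared probability interface", {
  # moderate separation keeps the classes overlapping, so logistic
  # regression converges without complete separation
  sim <- simulate_meta_features(n = 200, separation = 0.25, seed = 21)
  for (alg in c("gnb", "lr", "adaboost", "gbdt", "xgboost")) {
    mm <- fit_meta(alg, sim$X, sim$y, seed = 4L)
    expect_s3_class(mm, "meta_model")
    p <- predict_meta(mm, sim$X)
    expect_length(p, 200L)
    expect_true(all(p >= 0 & p <= 1))
    expect_gt(auc_score(sim$y, p), 0.85)
  }
  expect_error(fit_meta("svm", sim$X, sim$y))
})

test_that("the hand-written AdaBoost behaves like exponential-loss boosting", {
  sim <- simulate_meta_features(n = 100, separation = 0.7, seed = 8)
  fit <- pepstack:::adaboost_stumps(sim$X, sim$y, n_rounds = 30L)
  expect_true(length(fit$stumps) >= 1L)
  # stump weights are positive once error < 1/2 is achievable
  alphas <- vapply(fit$stumps, `[[`, 0, "alpha")
  expect_true(all(is.finite(alphas)))
  p <- pepstack:::predict_adaboost(fit, sim$X)
  expect_gt(auc_score(sim$y, p), 0.9)
  # a single perfectly separating feature is found in one round
  X1 <- cbind(c(rep(0, 10), rep(1, 10)), runif(20))
  y1 <- rep(c(0L, 1L), each = 10)
  f1 <- pepstack:::adaboost_stumps(X1, y1, n_rounds = 10L)
  p1 <- pepstack:::predict_adaboost(f1, X1)
  expect_equal(as.integer(p1 >= 0.5), y1)
})

test_that("out-of-fold meta-features align rows, folds and labels", {
  recs <- simulate_peptides(n_pos = 20, n_neg = 20,
                            length_range = c(10L, 25L), seed = 5)
  mf <- make_meta_features(
    recs, base_configs = quick_configs(epochs = 3L), k = 3L, seed = 2L,
    w2v_params = list(d = 4L, window = 3L, epochs = 10L), target_len = 25L)
  expect_named(mf$meta, c("id", META_FEATURES, "label", "fold"))
  expect_equal(mf$meta$id, recs$id)
  expect_equal(mf$meta$label, recs$label)
  expect_setequal(unique(mf$meta$fold), 1:3)
  for (col in META_FEATURES) {
    expect_false(anyNA(mf$meta[[col]]))
    expect_true(all(mf$meta[[col]] >= 0 & mf$meta[[col]] <= 1))
  }
  # fold assignment is stratified
  for (f in 1:3) {
    n1 <- sum(mf$meta$label[mf$fold == f])
    n0 <- sum(1 - mf$meta$label[mf$fold == f])
    expect_lte(abs(n1 - n0), 1L)
  }
  # reproducible for the same seed
  mf2 <- make_meta_features(
    recs, base_configs = quick_configs(epochs = 3L), k = 3L, seed = 2L,
    w2v_params = list(d = 4L, window = 3L, epochs = 10L), target_len = 25L)
  expect_equal(mf$meta, mf2$meta)
})

test_that("meta-feature extraction rejects unlabeled or misconfigured input", {
  recs <- simulate_peptides(n_pos = 5, n_neg = 5, length_range = c(8L, 12L),
                            seed = 1)
  bad <- recs; bad$label[1] <- NA
  expect_error(make_meta_features(bad, quick_configs(), k = 2L), "label")
  cfgs <- quick_configs()[c("onehot", "aaindex")]
  expect_error(make_meta_features(recs, cfgs, k = 2L), "four encoders")
})

test_that("the stacked pipeline trains, reports CV and predicts end to end", {
  recs <- simulate_peptides(n_pos = 30, n_neg = 30,
                            length_range = c(10L, 30L), seed = 7)
  fit <- pepstack_fit(
    recs, base_configs = quick_configs(epochs = 8L), k = 3L, seed = 3L,
    w2v_params = list(d = 8L, window = 3L, epochs = 30L), target_len = 30L)
  expect_s3_class(fit, "pepstack_model")
  expect_named(fit$base_models, ENCODER_IDS)
  expect_s3_class(fit$cv, "metrics_report")
  expect_equal(nrow(fit$cv), 4L)  # 3 folds + mean row
  expect_named(fit$base_cv_auc, ENCODER_IDS)
  expect_true(all(fit$base_cv_auc >= 0 & fit$base_cv_auc <= 1))

  preds <- predict(fit, recs)
  expect_named(preds, c("id", META_FEATURES, "p_meta", "label"))
  expect_equal(preds$id, recs$id)
  expect_true(all(preds$p_meta >= 0 & preds$p_meta <= 1))
  expect_equal(preds$label, as.integer(preds$p_meta >= 0.5))
  # resubstitution performance on an easy motif problem is strong
  expect_gt(auc_score(recs$label, preds$p_meta), 0.9)
  expect_identical(stacked_predict(fit, recs[1:4, ]), predict(fit, recs[1:4, ]))

  td <- generics::tidy(fit)
  expect_equal(nrow(td), 3L)
  gl <- generics::glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_train, 60L)
  expect_equal(gl$k, 3L)
  expect_equal(gl$meta, "gnb")
})

test_that("saved models reload and predict identically", {
  recs <- simulate_peptides(n_pos = 16, n_neg = 16,
                            length_range = c(8L, 20L), seed = 9)
  fit <- pepstack_fit(
    recs, base_configs = quick_configs(epochs = 3L), k = 2L, seed = 1L,
    w2v_params = list(d = 4L, window = 3L, epochs = 10L), target_len = 20L)
  dir <- withr::local_tempdir()
  save_pepstack_model(fit, dir)
  expect_true(file.exists(file.path(dir, "model.rds")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "gnb.json")))
  back <- load_pepstack_model(dir)
  expect_identical(predict(back, recs), predict(fit, recs))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$meta, "gnb")
  expect_equal(manifest$k, 2L)
  expect_error(load_pepstack_model(file.path(dir, "nope")), "model.rds")
})
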