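# helper: a linearly separable toy set of one-hot encoded peptides where the
# positive class always contains a W at a variable position
separable_set <- function(n = 24L, seed = 1L) {
  set.seed(seed)
  seqs <- replicate(n, paste(sample(setdiff(AA_ALPHABET, "W"), 12,
                                    replace = TRUE), collapse = ""))
  y <- rep(c(1, 0), length.out = n)
  seqs[y == 1] <- vapply(seqs[y == 1], function(s) {
    pos <- sample(12, 1)
    substr(s, pos, pos) <- "W"
    s
  }, "")
  X <- lapply(seqs, function(s) encode_onehot(pad_sequence(s, 20L)))
  list(X = X, y = y)
}

test_that("configuration validation rejects impossible settings", {
  expect_error(cnn_config(kernel = 4L), "odd")
  expect_error(cnn_config(dropout = 1), "dropout")
  expect_error(cnn_config(epochs = 0L), "epochs")
  expect_error(cnn_config(pool_size = 0L), "pool_size")
  expect_error(cnn_config(encoder = "nope"))
  cfg <- cnn_config(encoder = "ggap", pool = "mean", pool_size = 4L)
  expect_s3_class(cfg, "cnn_config")
  expect_equal(cfg$pool_size, 4L)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(41)
  n <- 6L
  X <- lapply(seq_len(n), function(i) matrix(rnorm(9 * 3), 9, 3))
  y <- rep(c(1, 0), 3)
  for (pool in c("max", "mean")) for (psz in list(NULL, 2L)) {
    cfg <- cnn_config(filters = 4L, kernel = 3L, pool = pool,
                      pool_size = psz, dropout = 0, dense_units = 5L,
                      seed = 2L)
    geom <- pepstack:::cnn_geometry(9L, cfg)
    st <- pepstack:::im2col_stack(X, cfg$kernel)
    w <- pepstack:::with_seed(2L, pepstack:::init_weights(
      cfg$kernel * 3L, cfg$filters, geom$nw, cfg$dense_units))
    loss_at <- function(w) {
      p <- pepstack:::cnn_forward(w, st$x, n, geom, pool)
      -mean(y * log(p + 1e-12) + (1 - y) * log(1 - p + 1e-12))
    }
    fw <- pepstack:::cnn_forward(w, st$x, n, geom, pool, keep = TRUE)
    gr <- pepstack:::cnn_backward(w, fw, st$x, y, n, geom, pool, NULL)
    h <- 1e-6
    for (nm in c("W", "W1", "w2", "b")) {
      idx <- sample(length(w[[nm]]), min(4L, length(w[[nm]])))
      for (i in idx) {
        wp <- w; wp[[nm]][i] <- wp[[nm]][i] + h
        wm <- w; wm[[nm]][i] <- wm[[nm]][i] - h
        num <- (loss_at(wp) - loss_at(wm)) / (2 * h)
        expect_equal(as.numeric(gr[[nm]][i]), num, tolerance = 1e-4)
      }
    }
  }
})

test_that("training is bit-reproducible for a fixed seed", {
  d <- separable_set(16L)
  cfg <- cnn_config(filters = 8L, kernel = 3L, dense_units = 8L,
                    epochs = 3L, batch_size = 8L, seed = 7L)
  m1 <- train_cnn(d$X, d$y, cfg)
  m2 <- train_cnn(d$X, d$y, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$loss, m2$loss)
  m3 <- train_cnn(d$X, d$y, cnn_config(filters = 8L, kernel = 3L,
                                       dense_units = 8L, epochs = 3L,
                                       batch_size = 8L, seed = 8L))
  expect_false(identical(m1$weights$W, m3$weights$W))
})

test_that("training does not disturb the caller's random number stream", {
  d <- separable_set(12L)
  cfg <- cnn_config(filters = 4L, kernel = 3L, dense_units = 4L,
                    epochs = 2L, seed = 1L)
  set.seed(99)
  before <- runif(3)
  set.seed(99)
  invisible(train_cnn(d$X, d$y, cfg))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("the network learns a linearly separable motif problem", {
  d <- separable_set(40L, seed = 3L)
  cfg <- cnn_config(filters = 8L, kernel = 3L, dense_units = 16L,
                    dropout = 0.2, epochs = 60L, batch_size = 16L,
                    learning_rate = 3e-3, seed = 5L)
  fit <- train_cnn(d$X, d$y, cfg)
  p <- predict_proba(fit, d$X)
  expect_true(all(p >= 0 & p <= 1))
  expect_gte(auc_score(d$y, p), 0.95)
  # loss trends downward overall
  expect_lt(mean(fit$loss[56:60]), mean(fit$loss[1:5]))
})

test_that("memorisable data with no dropout drives training loss near zero", {
  d <- separable_set(8L, seed = 6L)
  cfg <- cnn_config(filters = 8L, kernel = 3L, dense_units = 16L,
                    dropout = 0, epochs = 120L, batch_size = 8L,
                    learning_rate = 5e-3, seed = 4L)
  fit <- train_cnn(d$X, d$y, cfg)
  expect_lt(fit$loss[length(fit$loss)], 0.05)
  p <- predict_proba(fit, d$X)
  expect_equal(as.integer(p >= 0.5), as.integer(d$y))
})

test_that("prediction guards against shape and encoder mismatches", {
  d <- separable_set(12L)
  cfg <- cnn_config(filters = 4L, kernel = 3L, dense_units = 4L,
                    epochs = 2L, seed = 1L)
  fit <- train_cnn(d$X, d$y, cfg)
  wrong_shape <- list(matrix(0, 10, 20))
  expect_error(predict_proba(fit, wrong_shape), "shape")
  wrong_encoder <- lapply(d$X, function(m) {
    attr(m, "encoder_id") <- "aaindex"; m
  })
  expect_error(predict_proba(fit, wrong_encoder), "mismatch")
  untrained <- build_cnn(cfg, c(20L, 20L))
  expect_warning(predict_proba(untrained, d$X), "untrained")
})

test_that("single-class training sets are rejected", {
  d <- separable_set(8L)
  cfg <- cnn_config(epochs = 1L)
  expect_error(train_cnn(d$X, rep(1, 8)), "config")
  expect_error(train_cnn(d$X, rep(1, 8), cfg), "single class")
  expect_error(train_cnn(d$X[1:3], d$y, cfg), "matching")
})

test_that("grid search picks the configuration with the best fold-mean AUC", {
  d <- separable_set(30L, seed = 9L)
  base <- cnn_config(filters = 4L, kernel = 3L, dense_units = 8L,
                     epochs = 4L, batch_size = 16L, seed = 2L)
  gs <- grid_search(d$X, d$y, space = list(filters = c(2L, 8L)),
                    base = base, k = 3L, seed = 1L)
  expect_equal(nrow(gs$results), 2L)
  expect_s3_class(gs$best_config, "cnn_config")
  best_row <- which.max(gs$results$mean_auc)
  expect_equal(gs$best_config$filters, gs$results$filters[best_row])
  # untouched fields come from the base configuration
  expect_equal(gs$best_config$epochs, 4L)
  expect_error(grid_search(d$X, d$y, space = list()), "non-empty")
})
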