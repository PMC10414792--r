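# --- stacked ensemble -------------------------------------------------------
#
# Four encoder-specific CNN base classifiers produce, for every training
# sample, an out-of-fold probability; the 4-column matrix of those
# probabilities (fixed order: onehot, aaindex, ggap, word2vec) trains the
# meta-learner. For new peptides, base models refit on the full training set
# feed the meta-learner directly.

META_FEATURES <- paste0("p_", ENCODER_IDS)

#' Default base-classifier configurations
#'
#' One [cnn_config()] per encoder: 32 filters, kernel 5, max pooling
#' (global for the positional encoders, window 4 for the dipeptide
#' encoder), dropout 0.5, dense 64.
#'
#' @param epochs,batch_size,learning_rate,seed Overrides applied to all four.
#' @return Named list of four `cnn_config`s (onehot, aaindex, ggap, word2vec).
#' @export
default_base_configs <- function(epochs = 50L, batch_size = 64L,
                                 learning_rate = 1e-3, seed = 1L) {
  cfgs <- lapply(ENCODER_IDS, function(e) {
    # the dipeptide encoder needs position-aware pooling (its signal is
    # which bins are set); the positional encoders pool globally
    cnn_config(encoder = e, pool_size = if (e == "ggap") 4L else NULL,
               epochs = epochs, batch_size = batch_size,
               learning_rate = learning_rate, seed = seed)
  })
  names(cfgs) <- ENCODER_IDS
  cfgs
}

# encode all records with every encoder; the word2vec table must be supplied
# (trained on the caller's training split)
encode_all <- function(records, w2v_table, g = 0L, target_len = 100L,
                       aaindex = aaindex_table()) {
  list(
    onehot   = encode_peptides(records, "onehot", target_len),
    aaindex  = encode_peptides(records, "aaindex", target_len, table = aaindex),
    ggap     = encode_peptides(records, "ggap", target_len, g = g),
    word2vec = encode_peptides(records, "word2vec", target_len,
                               table = w2v_table)
  )
}

#' Out-of-fold meta-features from the four base classifiers
#'
#' Assigns records to `k` stratified folds (one assignment shared by all
#' four encoders, so rows align sample-wise), trains each encoder's CNN on
#' every fold complement, and records the held-out predictions: row s holds
#' the four probabilities for sample s from models that never saw it. The
#' residue-embedding table is retrained per fold on that fold's training
#' part only, so no encoder leaks held-out information.
#'
#' @param records Labelled peptide tibble.
#' @param base_configs Named list of four [cnn_config()]s, one per encoder.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param g Gap size for the dipeptide encoder (default 0).
#' @param w2v_params List of [train_word2vec()] settings
#'   (`d`, `window`, `epochs`).
#' @param target_len Padded length (default 100).
#' @return A list: `meta` (tibble with `id`, `p_onehot`, `p_aaindex`,
#'   `p_ggap`, `p_word2vec`, `label`, `fold`), the `fold` assignment and the
#'   call parameters.
#' @export
make_meta_features <- function(records, base_configs = default_base_configs(),
                               k = 5L, seed = 1L, g = 0L,
                               w2v_params = list(d = 32L, window = 5L,
                                                 epochs = 100L),
                               target_len = 100L) {
  validate_peptides(records)
  if (!"label" %in% names(records) || any(is.na(records$label))) {
    abort("make_meta_features() needs a label for every record")
  }
  if (!identical(sort(names(base_configs)), sort(ENCODER_IDS))) {
    abort("base_configs must name all four encoders exactly once")
  }
  n <- nrow(records)
  fold <- stratified_folds(records$label, k, seed)
  aaind <- aaindex_table()
  # fold-independent encoders computed once
  fixed <- list(
    onehot  = encode_peptides(records, "onehot", target_len),
    aaindex = encode_peptides(records, "aaindex", target_len, table = aaind),
    ggap    = encode_peptides(records, "ggap", target_len, g = g)
  )
  meta <- matrix(NA_real_, n, 4L, dimnames = list(NULL, META_FEATURES))
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    padded_tr <- pad_sequence(records$sequence[tr], target_len)
    w2v <- train_word2vec(padded_tr, d = w2v_params$d,
                          window = w2v_params$window,
                          epochs = w2v_params$epochs,
                          seed = base_configs$word2vec$seed + f)
    emb_all <- encode_peptides(records, "word2vec", target_len, table = w2v)
    for (e in ENCODER_IDS) {
      X <- if (e == "word2vec") emb_all else fixed[[e]]
      cfg <- base_configs[[e]]
      cfg$seed <- cfg$seed + f          # fresh init per fold, still seeded
      cfg <- do.call(cnn_config, unclass(cfg))
      fit <- train_cnn(X[tr], records$label[tr], cfg)
      meta[te, paste0("p_", e)] <- predict_proba(fit, X[te])
    }
  }
  out <- tibble::as_tibble(meta)
  out$id <- records$id
  out$label <- records$label
  out$fold <- fold
  list(meta = out[, c("id", META_FEATURES, "label", "fold")],
       fold = fold, k = k, seed = seed, g = g, w2v_params = w2v_params,
       target_len = target_len)
}

#' Fit a meta-learner on the 4-column meta-features
#'
#' The Gaussian naive Bayes meta-learner ([gnb_fit()]) is the package's own
#' implementation; logistic regression delegates to [stats::glm()], GBDT and
#' XGBoost to the xgboost package (GBDT configured as classical gradient
#' boosting: exact greedy splits, no regularisation or subsampling), and
#' AdaBoost is a compact SAMME decision-stump booster (no R implementation
#' of AdaBoost is available as a dependency). All five share the probability
#' interface [predict_meta()].
#'
#' @param algorithm One of `"gnb"`, `"lr"`, `"adaboost"`, `"gbdt"`,
#'   `"xgboost"`.
#' @param X Numeric n x p meta-feature matrix.
#' @param y Binary labels.
#' @param seed Integer seed (used by the boosted learners).
#' @return A `meta_model` wrapper.
#' @export
fit_meta <- function(algorithm, X, y, seed = 1L) {
  algorithm <- match.arg(algorithm, c("gnb", "lr", "adaboost", "gbdt",
                                      "xgboost"))
  X <- as.matrix(X)
  y <- as.integer(y)
  fit <- switch(algorithm,
    gnb = gnb_fit(X, y),
    lr = {
      df <- as.data.frame(X); df$.y <- y
      stats::glm(.y ~ ., data = df, family = stats::binomial())
    },
    adaboost = adaboost_stumps(X, y, n_rounds = 50L),
    gbdt = with_seed(seed, xgboost::xgb.train(
      params = xgboost::xgb.params(
        objective = "binary:logistic", learning_rate = 0.1, max_depth = 3L,
        reg_lambda = 0, reg_alpha = 0, subsample = 1, colsample_bytree = 1,
        tree_method = "exact", nthread = 1L, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1L),
      nrounds = 100L, verbose = 0
    )),
    xgboost = with_seed(seed, xgboost::xgb.train(
      params = xgboost::xgb.params(objective = "binary:logistic",
                                   max_depth = 6L, nthread = 1L, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1L),
      nrounds = 50L, verbose = 0
    ))
  )
  structure(list(algorithm = algorithm, fit = fit, p = ncol(X)),
            class = "meta_model")
}

#' Predict class-1 probabilities from any fitted meta-learner
#'
#' @param model A `meta_model` from [fit_meta()].
#' @param X Meta-feature matrix (n x p).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_meta <- function(model, X) {
  stopifnot(inherits(model, "meta_model"))
  X <- as.matrix(X)
  switch(model$algorithm,
    gnb = gnb_predict_proba(model$fit, X),
    lr = {
      df <- as.data.frame(X)
      unname(stats::predict(model$fit, newdata = df, type = "response"))
    },
    adaboost = predict_adaboost(model$fit, X),
    gbdt = ,
    xgboost = as.numeric(stats::predict(model$fit, X))
  )
}

# SAMME AdaBoost with depth-1 threshold stumps; probabilities via the
# exponential-loss link P(y=1|x) = 1 / (1 + exp(-2 F(x)))
adaboost_stumps <- function(X, y, n_rounds = 50L) {
  n <- nrow(X)
  ypm <- ifelse(y == 1L, 1, -1)
  w <- rep(1 / n, n)
  stumps <- vector("list", n_rounds)
  for (t in seq_len(n_rounds)) {
    best <- NULL
    for (j in seq_len(ncol(X))) {
      xs <- sort(unique(X[, j]))
      if (length(xs) < 2L) next
      thr <- (xs[-1L] + xs[-length(xs)]) / 2
      for (th in thr) {
        for (pol in c(1, -1)) {
          pred <- ifelse(pol * (X[, j] - th) >= 0, 1, -1)
          err <- sum(w[pred != ypm])
          if (is.null(best) || err < best$err) {
            best <- list(j = j, th = th, pol = pol, err = err, pred = pred)
          }
        }
      }
    }
    if (is.null(best)) break
    err <- min(max(best$err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    w <- w * exp(-alpha * ypm * best$pred)
    w <- w / sum(w)
    stumps[[t]] <- list(j = best$j, th = best$th, pol = best$pol,
                        alpha = alpha)
    if (best$err <= 1e-10) { stumps <- stumps[seq_len(t)]; break }
  }
  structure(list(stumps = Filter(Negate(is.null), stumps)),
            class = "adaboost_stumps")
}

predict_adaboost <- function(fit, X) {
  f <- numeric(nrow(X))
  for (s in fit$stumps) {
    f <- f + s$alpha * ifelse(s$pol * (X[, s$j] - s$th) >= 0, 1, -1)
  }
  1 / (1 + exp(-2 * f))
}

#' Fit the full stacked neuropeptide classifier
#'
#' Runs the whole training workflow on a labelled peptide set: out-of-fold
#' meta-features from the four CNN base classifiers
#' ([make_meta_features()]), the meta-learner fit on those meta-features,
#' base models refit on the full training set for deployment, and a
#' leakage-free cross-validated performance report (the meta-learner is
#' refit per fold on the other folds' meta-feature rows).
#'
#' @inheritParams make_meta_features
#' @param meta Meta-learner tag, default `"gnb"` (see [fit_meta()]).
#' @return A `pepstack_model` with elements `base_models`, `w2v_table`,
#'   `meta_model`, `meta_features` (the out-of-fold tibble), `cv` (a
#'   `metrics_report` for the stacked model) and `base_cv_auc` (named vector
#'   of per-encoder out-of-fold AUCs).
#' @export
#' @examples
#' \donttest{
#' set.seed(1)
#' recs <- simulate_peptides(n_pos = 40, n_neg = 40, seed = 1)
#' cfgs <- default_base_configs(epochs = 5)
#' fit <- pepstack_fit(recs, base_configs = cfgs, k = 3, seed = 1,
#'                     w2v_params = list(d = 8, window = 5, epochs = 30))
#' glance(fit)
#' }
pepstack_fit <- function(records, base_configs = default_base_configs(),
                         k = 5L, seed = 1L, meta = "gnb", g = 0L,
                         w2v_params = list(d = 32L, window = 5L,
                                           epochs = 100L),
                         target_len = 100L) {
  mf <- make_meta_features(records, base_configs, k = k, seed = seed, g = g,
                           w2v_params = w2v_params, target_len = target_len)
  Xmeta <- as.matrix(mf$meta[, META_FEATURES])
  y <- mf$meta$label
  meta_model <- fit_meta(meta, Xmeta, y, seed = seed)

  # leakage-free stacked CV: refit the meta-learner per fold on the other
  # folds' out-of-fold rows and score the held-out fold
  oof_meta <- numeric(nrow(Xmeta))
  for (f in seq_len(mf$k)) {
    te <- mf$fold == f
    mm <- fit_meta(meta, Xmeta[!te, , drop = FALSE], y[!te], seed = seed)
    oof_meta[te] <- predict_meta(mm, Xmeta[te, , drop = FALSE])
  }
  per_fold <- lapply(seq_len(mf$k), function(f) {
    te <- mf$fold == f
    m <- compute_metrics(confusion(y[te], oof_meta[te]))
    m$auc <- auc_score(y[te], oof_meta[te])
    m$fold <- f
    m
  })
  per_fold <- dplyr::bind_rows(per_fold)
  means <- colMeans(per_fold[, c("sn", "sp", "acc", "mcc", "auc")])
  cv <- dplyr::bind_rows(
    per_fold[, c("fold", "sn", "sp", "acc", "mcc", "auc")],
    tibble(fold = NA_integer_, sn = means["sn"], sp = means["sp"],
           acc = means["acc"], mcc = means["mcc"], auc = means["auc"])
  )
  cv <- structure(cv, class = c("metrics_report", class(cv)), k = mf$k)

  base_cv_auc <- vapply(ENCODER_IDS, function(e) {
    auc_score(y, mf$meta[[paste0("p_", e)]])
  }, 0)

  # deployment models: refit on the full training set
  w2v_table <- train_word2vec(pad_sequence(records$sequence, target_len),
                              d = w2v_params$d, window = w2v_params$window,
                              epochs = w2v_params$epochs,
                              seed = base_configs$word2vec$seed)
  enc <- encode_all(records, w2v_table, g = g, target_len = target_len)
  base_models <- lapply(ENCODER_IDS, function(e) {
    train_cnn(enc[[e]], records$label, base_configs[[e]])
  })
  names(base_models) <- ENCODER_IDS

  structure(
    list(base_models = base_models, w2v_table = w2v_table,
         meta_model = meta_model, meta_features = mf$meta,
         oof_meta = oof_meta, cv = cv, base_cv_auc = base_cv_auc,
         k = mf$k, seed = seed, g = g, target_len = target_len,
         decision_threshold = 0.5, n_train = nrow(records)),
    class = "pepstack_model"
  )
}

#' Predict neuropeptide probabilities for new peptides
#'
#' Encodes each record with all four encoders, scores the four refit base
#' classifiers, and combines them with the meta-learner. A posterior of
#' exactly 0.5 is labelled positive.
#'
#' @param object A `pepstack_model`.
#' @param records Peptide tibble (labels not required).
#' @param ... Unused.
#' @return A tibble with `id`, the four base probabilities, `p_meta` and the
#'   0/1 `label` at threshold 0.5.
#' @export
predict.pepstack_model <- function(object, records, ...) {
  validate_peptides(records)
  enc <- encode_all(records, object$w2v_table, g = object$g,
                    target_len = object$target_len)
  probs <- vapply(ENCODER_IDS, function(e) {
    predict_proba(object$base_models[[e]], enc[[e]])
  }, numeric(nrow(records)))
  probs <- matrix(probs, nrow = nrow(records),
                  dimnames = list(NULL, META_FEATURES))
  p_meta <- predict_meta(object$meta_model, probs)
  out <- tibble::as_tibble(probs)
  out$id <- records$id
  out$p_meta <- p_meta
  out$label <- as.integer(p_meta >= object$decision_threshold)
  out[, c("id", META_FEATURES, "p_meta", "label")]
}

#' @rdname predict.pepstack_model
#' @param model A `pepstack_model`.
#' @export
stacked_predict <- function(model, records) {
  predict(model, records)
}

#' @export
print.pepstack_model <- function(x, ...) {
  m <- report_means(x$cv)
  cat("<pepstack_model> ", x$meta_model$algorithm, " meta-learner over 4 CNN",
      " base classifiers\n", sep = "")
  cat(sprintf("  trained on %d peptides, %d-fold CV: AUC %.3f, Acc %.3f\n",
              x$n_train, x$k, m$auc, m$acc))
  invisible(x)
}

#' Write predictions as TSV
#'
#' @param predictions Tibble from [predict.pepstack_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions_tsv <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
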