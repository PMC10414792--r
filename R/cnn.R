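# --- convolutional base classifiers -----------------------------------------
#
# One compact 1-D CNN per encoder: a single convolution along the first
# matrix axis (sequence positions, or dipeptide bins for the g-gap encoder)
# with the second axis as input channels, ReLU, local max (or mean) pooling
# of width `pool_size`, flatten, dropout, one dense ReLU layer and a sigmoid
# output. Pooling is local rather than global because the dipeptide encoder
# carries its signal in *which* bins are set; global pooling would erase bin
# identity entirely. Trained with Adam on binary cross-entropy. The
# convolution is evaluated as an im2col matrix product so the whole
# forward/backward pass is dense BLAS work; all randomness (weight init,
# shuffling, dropout) flows from one seed, making training bit-reproducible
# on a single thread.

#' Base-classifier hyperparameter configuration
#'
#' @param encoder Which encoder this CNN consumes
#'   (`"onehot"`, `"aaindex"`, `"ggap"`, `"word2vec"`).
#' @param filters Number of convolution filters.
#' @param kernel Convolution kernel size along the first axis; odd, `>= 1`.
#' @param pool Pooling operator: `"max"` (default) or `"mean"`.
#' @param pool_size Pooling window width (stride equals width); `NULL`
#'   (default) pools globally over all positions. Use a small window for
#'   encoders whose signal lives in specific rows (the dipeptide encoder),
#'   since global pooling is position-blind.
#' @param dropout Dropout probability on the pooled features, in `[0, 1)`.
#' @param dense_units Width of the dense hidden layer.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs, `>= 1`.
#' @param seed Integer seed governing weight init, shuffling and dropout.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(encoder = "onehot", filters = 32L, kernel = 5L,
                       pool = c("max", "mean"), pool_size = NULL, dropout = 0.5,
                       dense_units = 64L, learning_rate = 1e-3,
                       batch_size = 64L, epochs = 50L, seed = 1L) {
  pool <- match.arg(pool)
  encoder <- match.arg(encoder, ENCODER_IDS)
  if (kernel < 1L || kernel %% 2L == 0L) {
    abort("`kernel` must be an odd positive integer")
  }
  if (!is.null(pool_size) && pool_size < 1L) abort("`pool_size` must be >= 1")
  if (dropout < 0 || dropout >= 1) abort("`dropout` must be in [0, 1)")
  if (epochs < 1L) abort("`epochs` must be >= 1")
  structure(
    list(encoder = encoder, filters = as.integer(filters),
         kernel = as.integer(kernel), pool = pool,
         pool_size = if (is.null(pool_size)) NULL else as.integer(pool_size),
         dropout = dropout, dense_units = as.integer(dense_units),
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), seed = as.integer(seed)),
    class = "cnn_config"
  )
}

# column index template mapping an input matrix (rows x cols, column-major)
# to its im2col expansion: P x (kernel*cols), P = rows - kernel + 1
im2col_index <- function(rows, cols, kernel) {
  P <- rows - kernel + 1L
  if (P < 1L) abort("kernel larger than the input's first axis")
  j <- rep(seq_len(kernel), each = cols)           # kernel offset, slow
  cch <- rep(seq_len(cols), times = kernel)        # channel, fast
  offs <- (cch - 1L) * rows + (j - 1L)             # 0-based within column
  outer(seq_len(P), offs, `+`)
}

# stack the im2col expansions of a list of equally shaped matrices into one
# (n*P) x (kernel*cols) matrix, sample-major with position fastest
im2col_stack <- function(X, kernel) {
  d <- dim(X[[1L]])
  idx <- im2col_index(d[1L], d[2L], kernel)
  P <- nrow(idx)
  big <- matrix(0, length(X) * P, ncol(idx))
  for (s in seq_along(X)) {
    big[(s - 1L) * P + seq_len(P), ] <- X[[s]][idx]
  }
  list(x = big, P = P)
}

init_weights <- function(kC, filters, n_windows, dense_units) {
  glorot <- function(fin, fout) {
    matrix(runif(fin * fout, -1, 1) * sqrt(6 / (fin + fout)), fin, fout)
  }
  list(W = glorot(kC, filters), b = numeric(filters),
       W1 = glorot(n_windows * filters, dense_units),
       b1 = numeric(dense_units),
       w2 = glorot(dense_units, 1L), b2 = 0)
}

# number of conv output positions and pooling windows for an input length
cnn_geometry <- function(rows, config) {
  P <- rows - config$kernel + 1L
  if (P < 1L) abort("input first axis shorter than the convolution kernel")
  ps <- if (is.null(config$pool_size)) P else min(config$pool_size, P)
  nw <- P %/% ps
  list(P = P, ps = ps, nw = nw)
}

#' Build an untrained convolutional base classifier
#'
#' Instantiates the network for a given input shape with seeded Glorot
#' initial weights; [train_cnn()] does this internally, so calling it
#' directly is only needed for inspection.
#'
#' @param config A [cnn_config()].
#' @param input_shape Integer pair `(rows, cols)` of the encoder output.
#' @return An untrained `cnn_model`.
#' @export
build_cnn <- function(config, input_shape) {
  stopifnot(inherits(config, "cnn_config"), length(input_shape) == 2L)
  geom <- cnn_geometry(input_shape[1L], config)
  weights <- with_seed(config$seed,
    init_weights(config$kernel * input_shape[2L], config$filters, geom$nw,
                 config$dense_units))
  structure(
    list(config = config, input_shape = as.integer(input_shape),
         weights = weights, trained = FALSE, loss = numeric(0)),
    class = "cnn_model"
  )
}

# forward pass on a stacked im2col matrix; returns activations needed for
# backprop when `keep = TRUE`. geom = cnn_geometry() of the input.
cnn_forward <- function(weights, xcol, n, geom, pool, drop_mask = NULL,
                        keep = FALSE) {
  Fn <- ncol(weights$W)
  P <- geom$P; ps <- geom$ps; nw <- geom$nw
  Z <- xcol %*% weights$W
  Z <- Z + rep(weights$b, each = nrow(Z))
  ZM <- matrix(Z, nrow = P)                    # P x (n*F), sample fastest
  ZM2 <- ZM[seq_len(nw * ps), , drop = FALSE]
  dim(ZM2) <- c(ps, nw * n * Fn)               # one column per pooling window
  if (pool == "max") {
    imax <- max.col(t(ZM2), ties.method = "first")
    vals <- ZM2[cbind(imax, seq_along(imax))]
    valsr <- pmax(vals, 0)                     # ReLU commutes with max
    pool_aux <- list(imax = imax, vals = vals)
  } else {
    valsr <- .colMeans(pmax(ZM2, 0), ps, nw * n * Fn)
    pool_aux <- list(ZM2 = ZM2)
  }
  # reorder (window, sample, filter) -> sample x (window, filter)
  D0 <- matrix(aperm(array(valsr, c(nw, n, Fn)), c(2L, 1L, 3L)), n, nw * Fn)
  D <- if (is.null(drop_mask)) D0 else D0 * drop_mask
  H_pre <- D %*% weights$W1
  H_pre <- H_pre + rep(weights$b1, each = n)
  H <- pmax(H_pre, 0)
  o <- drop(H %*% weights$w2) + as.numeric(weights$b2)
  p <- stats::plogis(o)
  if (!keep) return(p)
  list(p = p, H = H, H_pre = H_pre, D = D, pool_aux = pool_aux)
}

cnn_backward <- function(weights, fw, xcol, y, n, geom, pool, drop_mask) {
  Fn <- ncol(weights$W)
  P <- geom$P; ps <- geom$ps; nw <- geom$nw
  dout <- matrix((fw$p - y) / n, n, 1L)
  dw2 <- crossprod(fw$H, dout)
  db2 <- sum(dout)
  dH <- dout %*% t(weights$w2)
  dH[fw$H_pre <= 0] <- 0
  dW1 <- crossprod(fw$D, dH)
  db1 <- colSums(dH)
  dD <- dH %*% t(weights$W1)
  if (!is.null(drop_mask)) dD <- dD * drop_mask
  # back to (window, sample, filter) ordering
  dvals <- as.vector(aperm(array(dD, c(n, nw, Fn)), c(2L, 1L, 3L)))
  K <- nw * n * Fn
  if (pool == "max") {
    dvals[fw$pool_aux$vals <= 0] <- 0          # ReLU gradient
    dZM2 <- matrix(0, ps, K)
    dZM2[cbind(fw$pool_aux$imax, seq_len(K))] <- dvals
  } else {
    dZM2 <- matrix(dvals / ps, ps, K, byrow = TRUE)
    dZM2[fw$pool_aux$ZM2 <= 0] <- 0
  }
  dZM <- matrix(0, P, n * Fn)
  dim(dZM2) <- c(nw * ps, n * Fn)
  dZM[seq_len(nw * ps), ] <- dZM2
  dZ <- matrix(as.vector(dZM), n * P, Fn)
  dW <- crossprod(xcol, dZ)
  db <- colSums(dZ)
  list(W = dW, b = db, W1 = dW1, b1 = db1, w2 = dw2, b2 = db2)
}

#' Train a convolutional base classifier
#'
#' Fits the CNN on encoded matrices with Adam-optimised binary
#' cross-entropy. Deterministic for a fixed `config$seed` on a single
#' thread: the same data and seed reproduce the same weights bit for bit.
#'
#' @param X List of encoded matrices, all the same shape (one encoder).
#' @param y Binary labels (0/1), one per matrix; both classes required.
#' @param config A [cnn_config()].
#' @return A trained `cnn_model` with the per-epoch training `loss` curve.
#' @export
train_cnn <- function(X, y, config) {
  stopifnot(inherits(config, "cnn_config"))
  y <- as.numeric(y)
  if (length(X) != length(y) || length(y) < 2L) {
    abort("need matching X and y with at least 2 samples")
  }
  if (length(unique(y)) < 2L) abort("training labels contain a single class")
  d <- dim(X[[1L]])
  st <- im2col_stack(X, config$kernel)
  n <- length(X); P <- st$P
  geom <- cnn_geometry(d[1L], config)
  model <- with_seed(config$seed, {
    w <- init_weights(config$kernel * d[2L], config$filters, geom$nw,
                      config$dense_units)
    opt <- lapply(list(W = dim(w$W), b = length(w$b), W1 = dim(w$W1),
                       b1 = length(w$b1), w2 = dim(w$w2), b2 = 1L),
                  adam_state)
    tstep <- 0L
    losses <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      eploss <- 0
      for (bt in batches) {
        m <- length(bt)
        rows <- rep((bt - 1L) * P, each = P) + seq_len(P)
        xb <- st$x[rows, , drop = FALSE]
        mask <- if (config$dropout > 0) {
          q <- geom$nw * config$filters
          matrix((runif(m * q) >= config$dropout) / (1 - config$dropout),
                 m, q)
        } else NULL
        fw <- cnn_forward(w, xb, m, geom, config$pool, mask, keep = TRUE)
        eps <- 1e-12
        eploss <- eploss - sum(y[bt] * log(fw$p + eps) +
                                 (1 - y[bt]) * log(1 - fw$p + eps))
        gr <- cnn_backward(w, fw, xb, y[bt], m, geom, config$pool, mask)
        tstep <- tstep + 1L
        for (nm in names(gr)) {
          upd <- adam_update(opt[[nm]], gr[[nm]], config$learning_rate, tstep)
          opt[[nm]] <- upd$state
          w[[nm]] <- w[[nm]] - upd$step
        }
      }
      losses[ep] <- eploss / n
    }
    structure(
      list(config = config, input_shape = d, weights = w, trained = TRUE,
           loss = losses),
      class = "cnn_model"
    )
  })
  model
}

#' Predict class-1 probabilities from a trained base classifier
#'
#' @param model A trained `cnn_model`.
#' @param X List of encoded matrices matching the model's input shape.
#' @return Numeric vector of probabilities in `[0, 1]`, one per input,
#'   in input order.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "cnn_model"))
  if (!model$trained) warn("predicting from an untrained model")
  d <- dim(X[[1L]])
  if (!identical(as.integer(d), as.integer(model$input_shape))) {
    abort(paste0("input shape ", d[1L], "x", d[2L],
                 " does not match the model's encoder (",
                 model$input_shape[1L], "x", model$input_shape[2L], ")"))
  }
  ids <- vapply(X, function(m) attr(m, "encoder_id") %||% NA_character_, "")
  if (any(!is.na(ids) & ids != model$config$encoder)) {
    abort(paste0("encoder mismatch: model is bound to '",
                 model$config$encoder, "'"))
  }
  st <- im2col_stack(X, model$config$kernel)
  geom <- cnn_geometry(model$input_shape[1L], model$config)
  cnn_forward(model$weights, st$x, length(X), geom, model$config$pool)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cnn_model <- function(x, ...) {
  cat("<cnn_model>", x$config$encoder, "input",
      paste(x$input_shape, collapse = "x"),
      if (x$trained) sprintf("trained (%d epochs, final loss %.4f)",
                             x$config$epochs, x$loss[length(x$loss)])
      else "untrained", "\n")
  invisible(x)
}

#' Grid search over CNN hyperparameters by cross-validated AUC
#'
#' Scores every combination in `space` by mean AUC over `k` stratified
#' folds and returns the winner; ties break toward the earliest enumerated
#' combination. The fold assignment is fixed by `seed` and shared across
#' combinations so scores are comparable.
#'
#' @param X,y Encoded matrices and binary labels.
#' @param space Named list of candidate vectors for [cnn_config()] fields
#'   (e.g. `list(filters = c(16, 32), kernel = c(3, 5))`).
#' @param base A [cnn_config()] supplying every field not in `space`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return A list with `best_config` and `results`, a tibble of one row per
#'   combination with its `mean_auc`.
#' @export
grid_search <- function(X, y, space, base = cnn_config(), k = 5L, seed = 1L) {
  if (length(space) == 0L || any(lengths(space) == 0L)) {
    abort("`space` must be a non-empty named list of non-empty vectors")
  }
  grid <- expand.grid(space, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  fold <- stratified_folds(y, k, seed)
  aucs <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- base
    for (nm in names(space)) cfg[[nm]] <- grid[[nm]][i]
    cfg <- do.call(cnn_config, unclass(cfg))
    mean(vapply(seq_len(k), function(f) {
      tr <- fold != f
      fit <- train_cnn(X[tr], y[tr], cfg)
      auc_score(y[!tr], predict_proba(fit, X[!tr]))
    }, 0))
  }, 0)
  best <- base
  for (nm in names(space)) best[[nm]] <- grid[[nm]][which.max(aucs)]
  best <- do.call(cnn_config, unclass(best))
  list(best_config = best,
       results = tibble::as_tibble(cbind(grid, mean_auc = aucs)))
}
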