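# --- Gaussian naive Bayes meta-learner --------------------------------------
#
# Implemented from first principles: per class and feature, a Gaussian with
# the sample mean and the population-divisor variance (divisor n_c) plus a
# smoothing floor; priors are class frequencies; posteriors are evaluated in
# log space for stability.

#' Fit a Gaussian naive Bayes classifier
#'
#' @param X Numeric matrix (n x p) of features (here: the four base-model
#'   probabilities).
#' @param y Binary labels (0/1); both classes required.
#' @param var_smoothing Additive variance floor. Default: `1e-9` times the
#'   largest per-feature variance pooled over all samples, which keeps
#'   zero-variance features from collapsing the likelihood.
#' @return A `gnb` object with `priors` (named, classes "0"/"1"), `means`
#'   and `variances` (2 x p matrices, rows "0"/"1") and `var_smoothing`.
#' @export
gnb_fit <- function(X, y, var_smoothing = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) != length(y)) abort("X and y sizes differ")
  if (length(unique(y)) < 2L) abort("gnb_fit() needs both classes present")
  pop_var <- function(m) colMeans(m * m) - colMeans(m)^2
  if (is.null(var_smoothing)) {
    var_smoothing <- 1e-9 * max(pop_var(X))
    if (var_smoothing <= 0) var_smoothing <- 1e-12
  }
  classes <- c(0L, 1L)
  means <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(X[y == cl, , drop = FALSE])
  }))
  vars <- do.call(rbind, lapply(classes, function(cl) {
    pop_var(X[y == cl, , drop = FALSE])
  })) + var_smoothing
  rownames(means) <- rownames(vars) <- c("0", "1")
  priors <- c(`0` = mean(y == 0L), `1` = mean(y == 1L))
  structure(
    list(priors = priors, means = means, variances = vars,
         var_smoothing = var_smoothing, p = ncol(X),
         features = colnames(X)),
    class = "gnb"
  )
}

#' Posterior probability of class 1 under a fitted Gaussian naive Bayes
#'
#' For each row x, computes `P(class 1 | x)` proportional to
#' `prior * prod_j Normal(x_j; mean_1j, var_1j)`, normalised over the two
#' classes in log space.
#'
#' @param fit A `gnb` object from [gnb_fit()].
#' @param X Numeric matrix (or vector of length p) of feature rows.
#' @return Numeric vector of class-1 posterior probabilities.
#' @export
gnb_predict_proba <- function(fit, X) {
  stopifnot(inherits(fit, "gnb"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != fit$p) abort("feature count does not match the fitted model")
  loglik <- function(cl) {
    mu <- fit$means[cl, ]; v <- fit$variances[cl, ]
    centered <- sweep(X, 2L, mu)
    rowSums(sweep(centered^2, 2L, -2 * v, `/`)) -
      0.5 * sum(log(2 * pi * v)) + log(fit$priors[cl])
  }
  l0 <- loglik("0"); l1 <- loglik("1")
  m <- pmax(l0, l1)
  exp(l1 - m) / (exp(l0 - m) + exp(l1 - m))
}

#' @export
print.gnb <- function(x, ...) {
  cat("<gnb> priors", sprintf("%.3f/%.3f", x$priors[1L], x$priors[2L]),
      "on", x$p, "features; var_smoothing", format(x$var_smoothing), "\n")
  invisible(x)
}

#' @rdname tidy.pepstack_model
#' @exportS3Method generics::tidy
tidy.gnb <- function(x, ...) {
  p <- x$p
  feats <- x$features %||% paste0("f", seq_len(p))
  tibble(
    class = rep(c(0L, 1L), each = p),
    feature = rep(feats, 2L),
    mean = c(x$means["0", ], x$means["1", ]),
    variance = c(x$variances["0", ], x$variances["1", ]),
    prior = rep(unname(x$priors), each = p)
  )
}
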