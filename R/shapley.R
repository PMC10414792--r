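# --- exact Shapley attribution over the meta-features -----------------------
#
# With only four meta-features, the Shapley value of the meta-learner's
# class-1 posterior can be computed exactly: all 2^4 = 16 coalitions are
# enumerated, and the value of a coalition S is the interventional
# (marginal-replacement) expectation over a background set — background rows
# with the coalition's columns overwritten by the explained point. No
# sampling is involved, so explanations are deterministic and satisfy the
# efficiency, dummy and symmetry axioms to floating-point accuracy.

#' Exact Shapley values of a model output at one point
#'
#' For each feature j,
#' `phi_j = sum_{S subset of N\\{j}} |S|! (p-|S|-1)! / p! * (v(S+j) - v(S))`
#' where `v(S)` is the mean of `f` over the background rows with the columns
#' in S replaced by `x`. Positive values push the prediction toward the
#' positive (neuropeptide) class.
#'
#' @param f A function mapping a numeric matrix (rows = points) to a numeric
#'   vector of model outputs.
#' @param x Numeric vector, the point to explain.
#' @param background Numeric matrix (m x p) of reference rows.
#' @return A `shap_explanation`: list with `phi` (named by feature),
#'   `base_value` (mean model output on the background) and `fx` (the model
#'   output at `x`). `sum(phi) == fx - base_value` up to 1e-9.
#' @export
#' @examples
#' f <- function(m) m %*% c(1, 2, 0, -1)
#' bg <- matrix(runif(40), 10, 4)
#' exact_shapley(f, c(0.9, 0.1, 0.5, 0.3), bg)
exact_shapley <- function(f, x, background) {
  background <- as.matrix(background)
  p <- length(x)
  if (nrow(background) < 1L || ncol(background) != p) {
    abort("background must be a non-empty matrix with one column per feature")
  }
  m <- nrow(background)
  n_sets <- 2L^p
  # v(S) for every coalition bitmask: mean over background rows with the
  # coalition columns set to x; all masks evaluated in one batched f() call
  masks <- lapply(seq_len(n_sets) - 1L, function(bits) {
    as.logical(bitwAnd(bits, 2L^(seq_len(p) - 1L)))
  })
  big <- do.call(rbind, lapply(masks, function(on) {
    comp <- background
    comp[, on] <- matrix(x[on], m, sum(on), byrow = TRUE)
    comp
  }))
  vals <- f(big)
  v <- vapply(seq_len(n_sets), function(i) {
    mean(vals[(i - 1L) * m + seq_len(m)])
  }, 0)
  sizes <- vapply(masks, function(m) sum(m), 0L)
  phi <- vapply(seq_len(p), function(j) {
    bit <- 2L^(j - 1L)
    without <- which(!vapply(masks, `[`, TRUE, j))
    sum(vapply(without, function(i) {
      s <- sizes[i]
      w <- factorial(s) * factorial(p - s - 1L) / factorial(p)
      w * (v[i + bit] - v[i])
    }, 0))
  }, 0)
  names(phi) <- colnames(background) %||% paste0("f", seq_len(p))
  structure(list(phi = phi, base_value = v[1L], fx = v[n_sets]),
            class = "shap_explanation")
}

#' @export
print.shap_explanation <- function(x, ...) {
  cat("<shap_explanation> fx =", format(x$fx, digits = 4),
      " base =", format(x$base_value, digits = 4), "\n")
  print(round(x$phi, 4))
  invisible(x)
}

#' Explain a stacked model's predictions over its four meta-features
#'
#' Computes one exact Shapley explanation per row of `X` against a
#' background set drawn from the model's out-of-fold meta-features (capped
#' at `max_background` rows by seeded subsampling).
#'
#' @param model A `pepstack_model` (or `meta_model` / `gnb`).
#' @param X Meta-feature matrix to explain; defaults to the model's own
#'   out-of-fold meta-features.
#' @param background Background matrix; defaults to `X` capped at
#'   `max_background` rows.
#' @param max_background Cap on background rows (default 200).
#' @param seed Seed for the background subsample.
#' @return A `shap_explanations` tibble: one row per explained sample with
#'   `phi_*` columns, `base_value` and `fx`.
#' @export
explain_model <- function(model, X = NULL, background = NULL,
                          max_background = 200L, seed = 1L) {
  mm <- if (inherits(model, "pepstack_model")) model$meta_model else model
  f <- if (inherits(mm, "meta_model")) {
    function(m) { colnames(m) <- META_FEATURES; predict_meta(mm, m) }
  } else if (inherits(mm, "gnb")) {
    function(m) gnb_predict_proba(mm, m)
  } else {
    abort("explain_model() needs a pepstack_model, meta_model or gnb")
  }
  if (is.null(X)) {
    if (!inherits(model, "pepstack_model")) {
      abort("X must be given unless `model` is a pepstack_model")
    }
    X <- as.matrix(model$meta_features[, META_FEATURES])
  }
  X <- as.matrix(X)
  if (is.null(background)) {
    background <- X
    if (nrow(background) > max_background) {
      keep <- with_seed(seed, sample.int(nrow(background), max_background))
      background <- background[keep, , drop = FALSE]
    }
  }
  ex <- lapply(seq_len(nrow(X)), function(i) {
    exact_shapley(f, X[i, ], background)
  })
  phi <- do.call(rbind, lapply(ex, `[[`, "phi"))
  out <- tibble::as_tibble(phi, .name_repair = ~ paste0("phi_", sub("^p_", "", colnames(phi))))
  out$base_value <- vapply(ex, `[[`, 0, "base_value")
  out$fx <- vapply(ex, `[[`, 0, "fx")
  structure(out, class = c("shap_explanations", class(out)),
            feature_values = X)
}

#' Mean absolute Shapley value per meta-feature
#'
#' The standard global-importance summary: component j is the mean over
#' samples of `|phi_j|`.
#'
#' @param explanations A `shap_explanations` tibble from [explain_model()],
#'   or a list of `shap_explanation`s.
#' @return A `shap_summary` tibble with columns `feature` and `mean_abs_phi`,
#'   in the frozen meta-feature order.
#' @export
summarize_shap <- function(explanations) {
  if (inherits(explanations, "shap_explanations")) {
    phi <- as.matrix(explanations[, grep("^phi_", names(explanations))])
  } else if (is.list(explanations) && length(explanations) > 0L &&
             inherits(explanations[[1L]], "shap_explanation")) {
    phi <- do.call(rbind, lapply(explanations, `[[`, "phi"))
    colnames(phi) <- paste0("phi_", sub("^p_", "", colnames(phi)))
  } else {
    abort("summarize_shap() needs explanations from explain_model()")
  }
  out <- tibble(
    feature = sub("^phi_", "", colnames(phi)),
    mean_abs_phi = unname(colMeans(abs(phi)))
  )
  structure(out, class = c("shap_summary", class(out)), phi = phi)
}
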