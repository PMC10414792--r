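# --- broom-style tidiers -----------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods for fitted stacked models
#'
#' `tidy()` on a `pepstack_model` returns the per-fold cross-validated
#' metrics; on a `gnb` it returns the per-class, per-feature Gaussian
#' parameters. `glance()` returns a one-row model summary with the
#' fold-averaged metrics and the per-encoder out-of-fold AUCs.
#'
#' @param x A `pepstack_model` or `gnb`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.pepstack_model <- function(x, ...) {
  out <- x$cv[!is.na(x$cv$fold), ]
  tibble::as_tibble(out)
}

#' @rdname tidy.pepstack_model
#' @exportS3Method generics::glance
glance.pepstack_model <- function(x, ...) {
  m <- report_means(x$cv)
  tibble(
    n_train = x$n_train, k = x$k, meta = x$meta_model$algorithm,
    auc = m$auc, acc = m$acc, sn = m$sn, sp = m$sp, mcc = m$mcc,
    auc_onehot = x$base_cv_auc[["onehot"]],
    auc_aaindex = x$base_cv_auc[["aaindex"]],
    auc_ggap = x$base_cv_auc[["ggap"]],
    auc_word2vec = x$base_cv_auc[["word2vec"]]
  )
}
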