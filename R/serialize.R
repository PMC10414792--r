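# --- model persistence -------------------------------------------------------

#' Save a fitted stacked model to a directory
#'
#' Writes the R-native serialized model (`model.rds`), a JSON manifest with
#' the run configuration, the Gaussian naive Bayes parameters as JSON when
#' that meta-learner is used, and the out-of-fold meta-features as TSV.
#'
#' @param model A `pepstack_model`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_pepstack_model <- function(model, dir) {
  stopifnot(inherits(model, "pepstack_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  manifest <- list(
    package = "pepstack",
    meta = model$meta_model$algorithm,
    k = model$k, seed = model$seed, g = model$g,
    target_len = model$target_len, n_train = model$n_train,
    decision_threshold = model$decision_threshold,
    base_configs = lapply(model$base_models, function(m) unclass(m$config)),
    cv_means = as.list(report_means(model$cv))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (model$meta_model$algorithm == "gnb") {
    g <- model$meta_model$fit
    jsonlite::write_json(
      list(priors = as.list(g$priors), means = g$means,
           variances = g$variances, var_smoothing = g$var_smoothing),
      file.path(dir, "gnb.json"), auto_unbox = TRUE, digits = NA)
  }
  utils::write.table(model$meta_features, file.path(dir, "meta_features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Load a stacked model saved by [save_pepstack_model()]
#'
#' @param dir Model directory.
#' @return The `pepstack_model`.
#' @export
load_pepstack_model <- function(dir) {
  path <- file.path(dir, "model.rds")
  if (!file.exists(path)) abort(paste0("no model.rds under ", dir))
  model <- readRDS(path)
  if (!inherits(model, "pepstack_model")) abort("not a pepstack model")
  model
}
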