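# --- plotting ----------------------------------------------------------------

#' Plot a ROC curve
#'
#' @param y Binary labels; `scores` predicted scores.
#' @param scores Predicted scores.
#' @return A ggplot object with the ROC curve and the AUC in the subtitle.
#' @export
plot_roc <- function(y, scores) {
  pts <- roc_points(y, scores)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2166AC") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - Sp)", y = "True positive rate (Sn)",
      title = "ROC curve",
      subtitle = sprintf("AUC = %.3f", auc_score(y, scores))
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.metrics_report <- function(object, ...) {
  df <- object[!is.na(object$fold), ]
  long <- tibble(
    fold = rep(df$fold, 5L),
    metric = rep(c("sn", "sp", "acc", "mcc", "auc"), each = nrow(df)),
    value = c(df$sn, df$sp, df$acc, df$mcc, df$auc)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, height = 0, size = 1.5,
                         colour = "#2166AC") +
    ggplot2::labs(x = NULL, y = "per-fold value",
                  title = sprintf("%d-fold cross-validation metrics",
                                  attr(object, "k"))) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.shap_summary <- function(object, ...) {
  df <- object
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_abs_phi,
                                   y = .data$feature)) +
    ggplot2::geom_col(fill = "#B2182B", width = 0.6) +
    ggplot2::labs(x = "mean |Shapley value|", y = NULL,
                  title = "Meta-feature importance") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
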