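# --- binary-classification evaluation ---------------------------------------

#' Confusion counts at a probability threshold
#'
#' Predicts class 1 where `score >= threshold` (ties go to the positive
#' class) and tallies the counts against the true labels.
#'
#' @param y Binary labels (0/1).
#' @param scores Predicted scores/probabilities, same length as `y`.
#' @param threshold Decision threshold (default 0.5).
#' @return A `confusion_counts` list with `tp`, `tn`, `fp`, `fn`.
#' @export
#' @examples
#' confusion(c(1, 1, 0, 0), c(0.9, 0.2, 0.8, 0.1))
confusion <- function(y, scores, threshold = 0.5) {
  if (length(y) != length(scores) || length(y) < 1L) {
    abort("`y` and `scores` must have the same positive length")
  }
  pred <- as.integer(scores >= threshold)
  y <- as.integer(y)
  structure(
    list(tp = sum(pred == 1L & y == 1L), tn = sum(pred == 0L & y == 0L),
         fp = sum(pred == 1L & y == 0L), fn = sum(pred == 0L & y == 1L)),
    class = "confusion_counts"
  )
}

#' Threshold metrics from confusion counts
#'
#' Computes sensitivity Sn = TP/(TP+FN), specificity Sp = TN/(TN+FP),
#' accuracy Acc = (TP+TN)/N and the Matthews correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). A zero
#' factor in the MCC denominator yields MCC = 0 (with a warning); an empty
#' positive (or negative) class yields Sn (or Sp) of `NA` with a warning.
#'
#' @param counts A `confusion_counts` object or a list with `tp,tn,fp,fn`.
#' @return A one-row tibble with columns `sn`, `sp`, `acc`, `mcc`.
#' @export
#' @examples
#' compute_metrics(confusion(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)))
compute_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) abort("no samples in the confusion counts")
  sn <- if (tp + fn == 0) { warn("no positives: Sn undefined"); NA_real_ }
        else tp / (tp + fn)
  sp <- if (tn + fp == 0) { warn("no negatives: Sp undefined"); NA_real_ }
        else tn / (tn + fp)
  acc <- (tp + tn) / total
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) {
    warn("degenerate confusion matrix: MCC set to 0")
    0
  } else (tp * tn - fp * fn) / sqrt(denom)
  tibble(sn = sn, sp = sp, acc = acc, mcc = mcc)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a uniformly chosen
#' positive receives a higher score than a uniformly chosen negative, with
#' score ties counted one half.
#'
#' @param y Binary labels (0/1); both classes must be present.
#' @param scores Real-valued scores.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc_score(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.1))
auc_score <- function(y, scores) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) abort("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @param y Binary labels; `scores` real scores.
#' @param scores Predicted scores.
#' @return A tibble with columns `threshold`, `fpr`, `tpr`, one row per
#'   distinct score plus the endpoints, suitable for plotting or TSV export.
#' @export
roc_points <- function(y, scores) {
  y <- as.integer(y)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; sc <- scores[ord]
  tp <- cumsum(ys); fp <- cumsum(1L - ys)
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)
  tibble(
    threshold = c(Inf, sc[keep]),
    fpr = c(0, fp[keep] / max(1L, sum(y == 0L))),
    tpr = c(0, tp[keep] / max(1L, sum(y == 1L)))
  )
}

#' Stratified k-fold cross-validation of a scoring pipeline
#'
#' Splits labelled records into `k` stratified folds, calls
#' `fit(train_records)` on each training part and `score(fitted,
#' test_records)` on the held-out part, and reports Sn/Sp/Acc/MCC/AUC per
#' fold plus their unweighted means.
#'
#' @param records Labelled peptide tibble (or any data frame with a `label`
#'   column that `fit`/`score` understand).
#' @param fit Function `train_records -> fitted object`.
#' @param score Function `(fitted, test_records) -> numeric scores` for the
#'   held-out records.
#' @param k Number of folds.
#' @param seed Integer seed for the fold assignment.
#' @param threshold Decision threshold for the threshold metrics.
#' @return A `metrics_report`: tibble with one row per fold and a final
#'   `"mean"` row, columns `fold`, `sn`, `sp`, `acc`, `mcc`, `auc`.
#' @export
cross_validate <- function(records, fit, score, k = 5L, seed = 1L,
                           threshold = 0.5) {
  if (!"label" %in% names(records) || any(is.na(records$label))) {
    abort("cross_validate() needs a label for every record")
  }
  fold <- stratified_folds(records$label, k, seed)
  rows <- lapply(seq_len(k), function(f) {
    tr <- records[fold != f, , drop = FALSE]
    te <- records[fold == f, , drop = FALSE]
    fitted <- fit(tr)
    sc <- score(fitted, te)
    m <- compute_metrics(confusion(te$label, sc, threshold))
    m$auc <- auc_score(te$label, sc)
    m$fold <- f
    m
  })
  per_fold <- dplyr::bind_rows(rows)
  means <- dplyr::summarise(per_fold, dplyr::across(c("sn", "sp", "acc",
                                                      "mcc", "auc"), mean))
  out <- dplyr::bind_rows(
    per_fold[, c("fold", "sn", "sp", "acc", "mcc", "auc")],
    tibble(fold = NA_integer_, sn = means$sn, sp = means$sp, acc = means$acc,
           mcc = means$mcc, auc = means$auc)
  )
  structure(out, class = c("metrics_report", class(out)), k = k)
}

#' Headline (fold-averaged) metrics of a report
#'
#' @param report A `metrics_report` from [cross_validate()].
#' @return One-row tibble with the fold-averaged `sn`, `sp`, `acc`, `mcc`,
#'   `auc`.
#' @export
report_means <- function(report) {
  stopifnot(inherits(report, "metrics_report"))
  report[is.na(report$fold), c("sn", "sp", "acc", "mcc", "auc")]
}
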