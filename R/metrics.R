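# Confusion-matrix metrics and rank-based AUC.

#' Confusion-matrix metrics for binary predictions
#'
#' Counts TP/FP/FN/TN with class 1 as positive and derives accuracy,
#' precision, recall and F1. Undefined rates (zero denominators) are
#' returned as 0 and flagged via the `degenerate` column with a warning.
#'
#' @param y_true,y_pred Binary 0/1 vectors of equal length.
#' @return One-row tibble: `tp`, `fp`, `fn`, `tn`, `accuracy`, `precision`,
#'   `recall`, `f1`, `n`, `support_pos`, `support_neg`, `degenerate`.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0L) abort("empty input", class = "fvepnet_empty_input")
  if (length(y_true) != length(y_pred)) {
    abort("y_true and y_pred must have equal length",
          class = "fvepnet_bad_input")
  }
  if (!all(c(y_true, y_pred) %in% c(0, 1))) {
    abort("inputs must be binary 0/1", class = "fvepnet_bad_input")
  }
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0)
  n <- length(y_true)
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  if (degenerate) warn("a metric denominator was zero; reported as 0",
                       class = "fvepnet_degenerate_metric")
  tibble(tp = tp, fp = fp, fn = fn, tn = tn,
         accuracy = (tp + tn) / n,
         precision = precision, recall = recall, f1 = f1,
         n = n, support_pos = tp + fn, support_neg = tn + fp,
         degenerate = degenerate)
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Probability that a random positive outranks a random negative, with ties
#' receiving midranks.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary 0/1 vector.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) {
    abort("both classes must be present for AUC",
          class = "fvepnet_one_class")
  }
  r <- rank(scores)          # ties -> midranks
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics of a fitted model on records
#'
#' @param fit An `mcac_fit`.
#' @param records Records with labels in `fit$class_levels`.
#' @param positive Which class counts as positive (default `"normal"`,
#'   matching the majority-class convention of the screening setting;
#'   switchable).
#' @return One-row tibble from [confusion_metrics()] plus `auc` on the
#'   positive-class probability.
#' @export
evaluate_classification <- function(fit, records, positive = "normal") {
  records <- records[records$label %in% fit$class_levels, , drop = FALSE]
  pred <- predict(fit, records)
  y_true <- as.numeric(records$label == positive)
  y_pred <- as.numeric(pred$pred_class == positive)
  m <- confusion_metrics(y_true, y_pred)
  m$auc <- auc_score(pred[[paste0("p_", positive)]], y_true)
  m
}
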