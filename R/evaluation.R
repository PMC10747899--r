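# Classification metrics for the binary anomaly task: confusion matrix,
# per-class precision/recall/F1 with macro and support-weighted aggregates,
# accuracy and its complement (the tuning objective), Cohen's kappa (the
# tracked indicator), ROC/PR threshold sweeps, and reconstruction of the
# integer confusion matrix from printed per-class report rows.
#
# Class 1 (anomalous) is the positive class throughout.

check_binary <- function(x, nm) {
  if (!all(x %in% c(0, 1))) stop(nm, " must be binary 0/1")
}

#' Confusion matrix for binary labels
#'
#' @param y_true,y_pred Equal-length binary 0/1 vectors; class 1 = anomalous
#'   is the positive class.
#' @return A `confusion_matrix` with integer fields `tn`, `fp`, `fn`, `tp`
#'   and per-class supports.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred have different lengths")
  }
  check_binary(y_true, "y_true")
  check_binary(y_pred, "y_pred")
  cm_from_counts(tn = sum(y_true == 0 & y_pred == 0),
                 fp = sum(y_true == 0 & y_pred == 1),
                 fn = sum(y_true == 1 & y_pred == 0),
                 tp = sum(y_true == 1 & y_pred == 1))
}

#' Build a confusion matrix directly from counts
#'
#' @param tn,fp,fn,tp Non-negative integer cell counts.
#' @return A `confusion_matrix`.
#' @export
cm_from_counts <- function(tn, fp, fn, tp) {
  stopifnot(tn >= 0, fp >= 0, fn >= 0, tp >= 0)
  structure(list(tn = as.integer(tn), fp = as.integer(fp),
                 fn = as.integer(fn), tp = as.integer(tp),
                 support = c(normal = as.integer(tn + fp),
                             anomalous = as.integer(fn + tp))),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2, 2, byrow = TRUE,
              dimnames = list(true = c("normal", "anomalous"),
                              predicted = c("normal", "anomalous")))
  print(m)
  invisible(x)
}

cm_total <- function(cm) cm$tn + cm$fp + cm$fn + cm$tp

#' Per-class and aggregate classification report
#'
#' Standard definitions with the anomalous class positive: per-class
#' precision, recall and F1 (harmonic mean), accuracy, unweighted macro
#' averages and support-weighted averages. Zero-support or zero-denominator
#' metrics raise an error rather than silently returning 0, so degenerate
#' models surface during tuning.
#'
#' @param cm A `confusion_matrix`.
#' @return A `classification_report` list with fields `precision`, `recall`,
#'   `f1` (named per class), `accuracy`, `macro` and `weighted` (each with
#'   precision/recall/f1), and `support`.
#' @export
classification_report <- function(cm) {
  if (any(cm$support == 0)) stop("zero support for a class; metrics undefined")
  prec_den <- c(normal = cm$tn + cm$fn, anomalous = cm$tp + cm$fp)
  if (any(prec_den == 0)) {
    stop("no predictions for a class; precision undefined")
  }
  precision <- c(normal = cm$tn / (cm$tn + cm$fn),
                 anomalous = cm$tp / (cm$tp + cm$fp))
  recall <- c(normal = cm$tn / (cm$tn + cm$fp),
              anomalous = cm$tp / (cm$tp + cm$fn))
  f1 <- 2 * precision * recall / (precision + recall)
  w <- cm$support / cm_total(cm)
  structure(list(
    precision = precision, recall = recall, f1 = f1,
    accuracy = (cm$tn + cm$tp) / cm_total(cm),
    macro = c(precision = mean(precision), recall = mean(recall),
              f1 = mean(f1)),
    weighted = c(precision = sum(w * precision), recall = sum(w * recall),
                 f1 = sum(w * f1)),
    support = cm$support
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  out <- rbind(Precision = c(x$precision, Accuracy = x$accuracy,
                             Macro = x$macro[["precision"]],
                             Weighted = x$weighted[["precision"]]),
               Recall = c(x$recall, x$accuracy, x$macro[["recall"]],
                          x$weighted[["recall"]]),
               `F1 score` = c(x$f1, x$accuracy, x$macro[["f1"]],
                              x$weighted[["f1"]]))
  print(round(out, 6))
  cat("support:", paste(names(x$support), x$support, collapse = ", "), "\n")
  invisible(x)
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(zo - ze) / (1 - ze)` where `zo` is the
#' observed agreement (accuracy) and `ze` the expected agreement from the
#' marginal products.
#'
#' @param cm A `confusion_matrix` with positive total.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(cm) {
  n <- cm_total(cm)
  if (n == 0) stop("empty confusion matrix")
  zo <- (cm$tn + cm$tp) / n
  ze <- ((cm$tn + cm$fp) * (cm$tn + cm$fn) +
           (cm$fn + cm$tp) * (cm$fp + cm$tp)) / n^2
  if (abs(1 - ze) < 1e-15) {
    stop("degenerate single-class marginals; kappa undefined")
  }
  (zo - ze) / (1 - ze)
}

#' Error rate (the tuning objective)
#'
#' @param cm A `confusion_matrix`.
#' @return `1 - accuracy`.
#' @export
error_rate <- function(cm) {
  n <- cm_total(cm)
  if (n == 0) stop("empty confusion matrix")
  1 - (cm$tn + cm$tp) / n
}

#' Reconstruct an integer confusion matrix from printed report rows
#'
#' Given per-class precision, recall and integer supports as printed in a
#' rounded report table, searches all integer per-class correct-count pairs
#' (0..support), picks the pair minimizing the summed absolute deviation
#' from the printed recalls, and verifies that the implied precisions
#' reproduce the printed ones to the printed precision (6 decimals).
#'
#' @param precision_by_class Numeric length-2 vector (normal, anomalous).
#' @param recall_by_class Numeric length-2 vector (normal, anomalous).
#' @param support_by_class Integer length-2 vector (normal, anomalous).
#' @param tol Verification tolerance on recalls and precisions (default
#'   `5e-7`, half a unit in the 6th printed decimal).
#' @return A `confusion_matrix`.
#' @export
reconstruct_confusion <- function(precision_by_class, recall_by_class,
                                  support_by_class, tol = 5e-7) {
  stopifnot(length(precision_by_class) == 2, length(recall_by_class) == 2,
            length(support_by_class) == 2, all(support_by_class >= 1))
  s <- as.integer(support_by_class)
  # correct counts per class: tn in 0..s1, tp in 0..s2
  tn_cand <- 0:s[1]
  tp_cand <- 0:s[2]
  dev_tn <- abs(tn_cand / s[1] - recall_by_class[1])
  dev_tp <- abs(tp_cand / s[2] - recall_by_class[2])
  tn <- tn_cand[which.min(dev_tn)]
  tp <- tp_cand[which.min(dev_tp)]
  if (min(dev_tn) > tol || min(dev_tp) > tol) {
    stop("no integer confusion matrix reproduces the printed recalls")
  }
  cm <- cm_from_counts(tn = tn, fp = s[1] - tn, fn = s[2] - tp, tp = tp)
  rep_ <- classification_report(cm)
  if (any(abs(rep_$precision - precision_by_class) > tol)) {
    stop("printed precisions are inconsistent with the recovered matrix")
  }
  cm
}

#' ROC and PR points by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores (plus sentinels)
#' and records false/true-positive rates and precision/recall at each,
#' labeling positive when `score >= threshold`.
#'
#' @param y_true Binary 0/1 labels (both classes present for ROC).
#' @param scores Real-valued scores, higher = more anomalous.
#' @return A list with data frames `roc` (threshold, fpr, tpr) ordered by
#'   increasing fpr, `pr` (threshold, recall, precision), and trapezoidal
#'   areas `auc_roc` and `auc_pr`.
#' @export
curve_points <- function(y_true, scores) {
  if (length(y_true) != length(scores)) stop("length mismatch")
  check_binary(y_true, "y_true")
  if (length(unique(y_true)) < 2) {
    stop("ROC undefined for single-class truth")
  }
  np <- sum(y_true == 1)
  nn <- sum(y_true == 0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(th) {
    pred <- as.integer(scores >= th)
    tp <- sum(pred == 1 & y_true == 1)
    fp <- sum(pred == 1 & y_true == 0)
    c(fpr = fp / nn, tpr = tp / np,
      precision = if (tp + fp == 0) 1 else tp / (tp + fp))
  }, numeric(3)))
  roc <- data.frame(threshold = thr, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
  pr <- data.frame(threshold = thr, recall = pts[, "tpr"],
                   precision = pts[, "precision"])
  auc <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  list(roc = roc, pr = pr,
       auc_roc = auc(roc$fpr, roc$tpr),
       auc_pr = auc(pr$recall, pr$precision))
}

#' Write a classification report as CSV
#'
#' Layout mirrors a per-class report table: one row per metric with
#' per-class, accuracy, macro and weighted columns, plus a support row.
#'
#' @param report A `classification_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  df <- data.frame(
    metric = c("precision", "recall", "f1", "support"),
    normal = c(report$precision[["normal"]], report$recall[["normal"]],
               report$f1[["normal"]], report$support[["normal"]]),
    anomalous = c(report$precision[["anomalous"]], report$recall[["anomalous"]],
                  report$f1[["anomalous"]], report$support[["anomalous"]]),
    accuracy = c(rep(report$accuracy, 3), NA),
    macro_avg = c(report$macro, NA),
    weighted_avg = c(report$weighted, NA)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
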