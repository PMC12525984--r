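#' Classification evaluation report
#'
#' Confusion matrix and the standard derived metrics: accuracy (trace over
#' total), per-category precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
#' `F1 = 2PR/(P+R)`, their macro (or optionally support-weighted) averages,
#' and the macro one-vs-rest area under the ROC curve when continuous
#' scores are supplied.
#'
#' @param truth true category factor.
#' @param predicted predicted category factor (same levels).
#' @param scores optional N x C matrix of continuous per-category scores
#'   for AUC.
#' @param average `"macro"` (default) or `"weighted"` averaging of the
#'   per-category metrics.
#' @param set_name label for the evaluated set (cal/val/test).
#' @return object of class `eval_report`: `confusion` (true x predicted),
#'   `accuracy`, `precision`, `recall`, `f1`, `auc` (all on [0, 1]),
#'   `per_category` data frame (with an `undefined_precision` flag for
#'   categories never predicted, reported as 0).
#' @export
evaluate <- function(truth, predicted, scores = NULL,
                     average = c("macro", "weighted"), set_name = "test") {
  average <- match.arg(average)
  truth <- factor(truth)
  predicted <- factor(predicted, levels = levels(truth))
  stopifnot(length(truth) == length(predicted))
  cm <- table(truth = truth, predicted = predicted)
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  undefined <- (tp + fp) == 0
  if (any(undefined)) {
    warning("category never predicted: precision reported as 0 for ",
            paste(levels(truth)[undefined], collapse = ", "))
  }
  prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  rec <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  wts <- if (average == "macro") rep(1 / nlevels(truth), nlevels(truth))
         else as.numeric(rowSums(cm)) / total
  auc <- NA_real_
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    stopifnot(nrow(scores) == length(truth), ncol(scores) == nlevels(truth))
    aucs <- vapply(seq_len(nlevels(truth)), function(i) {
      resp <- truth == levels(truth)[i]
      if (all(resp) || !any(resp)) return(NA_real_)
      as.numeric(pROC::auc(pROC::roc(resp, scores[, i], quiet = TRUE,
                                     direction = "<", levels = c(FALSE, TRUE))))
    }, 1)
    auc <- sum(wts * aucs)
  }
  structure(list(
    confusion = cm,
    accuracy = sum(tp) / total,
    precision = sum(wts * prec), recall = sum(wts * rec), f1 = sum(wts * f1),
    auc = auc, average = average, set_name = set_name,
    per_category = data.frame(category = levels(truth),
                              precision = as.numeric(prec),
                              recall = as.numeric(rec), f1 = as.numeric(f1),
                              support = as.numeric(rowSums(cm)),
                              undefined_precision = as.logical(undefined))
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %s> accuracy %.2f%%, %s P %.3f R %.3f F1 %.3f%s\n",
              x$set_name, 100 * x$accuracy, x$average,
              x$precision, x$recall, x$f1,
              if (is.finite(x$auc)) sprintf(", AUC %.3f", x$auc) else ""))
  print(x$confusion)
  invisible(x)
}

#' F1 score from precision and recall
#'
#' The harmonic mean `2PR/(P+R)`; 0 when both are 0.
#'
#' @param precision,recall numeric vectors on [0, 1].
#' @return numeric F1 values.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}
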