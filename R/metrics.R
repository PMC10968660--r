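# Evaluation metrics for imbalanced binary classification.

#' Classification accuracy
#' @param y_true,y_pred equal-length vectors of class labels
#' @return fraction of correct predictions
#' @export
accuracy <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop_invalid("empty input")
  if (length(y_true) != length(y_pred)) stop_invalid("length mismatch")
  mean(as.character(y_true) == as.character(y_pred))
}

#' Support-weighted F1 score
#'
#' The F1 score is computed one-vs-rest for each class present in `y_true`
#' (precision and recall from that class's confusion counts, with F1 defined
#' as 0 when precision + recall is 0), then averaged with weights equal to
#' each class's support:
#' \deqn{F1_{wg} = \sum_c F1_c \cdot N_c / N}
#' This weighting keeps the score honest under class imbalance, where plain
#' accuracy rewards majority-class guessing.
#'
#' @param y_true,y_pred equal-length label vectors
#' @return weighted F1 in \[0, 1\]
#' @export
weighted_f1 <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop_invalid("empty input")
  if (length(y_true) != length(y_pred)) stop_invalid("length mismatch")
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  n <- length(y_true)
  classes <- unique(y_true)
  f1w <- 0
  for (cl in classes) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec <- if (tp + fp == 0L) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0L) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    f1w <- f1w + f1 * sum(y_true == cl) / n
  }
  f1w
}

#' Area under the ROC curve
#'
#' The midrank Mann-Whitney statistic on positive-class scores:
#' P(score_pos > score_neg) + P(tie)/2, over all positive/negative pairs.
#'
#' @param y_true binary labels; `positive` names the positive class (defaults
#'   to the first level of a factor, else `"positive"` when present, else the
#'   first unique value).
#' @param scores numeric scores, higher = more positive
#' @param positive the positive-class label
#' @return AUC in \[0, 1\]
#' @export
auc_score <- function(y_true, scores, positive = NULL) {
  if (length(y_true) != length(scores)) stop_invalid("length mismatch")
  yt <- as.character(y_true)
  if (is.null(positive)) {
    positive <- if (is.factor(y_true)) levels(y_true)[1L]
      else if ("positive" %in% yt) "positive" else yt[1L]
  }
  pos <- yt == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop_invalid("AUC undefined: both classes must be present")
  }
  r <- rank(scores)                 # midranks handle ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluation report row
#'
#' Bundles the evaluation of one selected feature set by one classifier:
#' accuracy, support-weighted F1, AUC, selected-feature count and the
#' selection wall time in seconds.
#'
#' @param accuracy,weighted_f1,auc rates in \[0, 1\]
#' @param n_selected selected-feature count
#' @param seconds selection wall time
#' @export
eval_report <- function(accuracy, weighted_f1, auc, n_selected, seconds = NA_real_) {
  rates <- c(accuracy = accuracy, weighted_f1 = weighted_f1, auc = auc)
  if (any(!is.na(rates) & (rates < 0 | rates > 1))) {
    stop_invalid("rates must lie in [0, 1]")
  }
  structure(list(accuracy = accuracy, weighted_f1 = weighted_f1, auc = auc,
                 n_selected = n_selected, seconds = seconds),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | weighted F1 %.4f | AUC %.4f | %d features | %.2fs\n",
              x$accuracy, x$weighted_f1, x$auc, x$n_selected, x$seconds))
  invisible(x)
}
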