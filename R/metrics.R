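# Confusion-matrix metrics and ROC/AUC for binary node classification.

#' Confusion counts
#'
#' @param calls Binary (0/1) vector of predicted classes.
#' @param labels Binary (0/1) vector of ground-truth classes, same length.
#' @return Named list with integers `tp`, `tn`, `fp`, `fn` (class
#'   `confusion_counts`).
#' @export
confusion <- function(calls, labels) {
  if (length(calls) != length(labels))
    stop("calls and labels differ in length (", length(calls), " vs ",
         length(labels), ")")
  stopifnot(all(calls %in% c(0, 1)), all(labels %in% c(0, 1)))
  structure(list(tp = sum(calls == 1 & labels == 1),
                 tn = sum(calls == 0 & labels == 0),
                 fp = sum(calls == 1 & labels == 0),
                 fn = sum(calls == 0 & labels == 1)),
            class = "confusion_counts")
}

# Safe ratio: zero-denominator metrics return 0 (flagged upstream) so
# result tables stay rectangular.
.safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Area under the ROC curve
#'
#' Threshold sweep over the unique scores with trapezoidal integration of
#' the ROC curve; equivalent to the rank statistic counting correctly
#' ordered (positive, negative) pairs with ties at half weight.
#'
#' @param probs Numeric scores.
#' @param labels Binary labels.
#' @return AUC in [0, 1]; 0 with a `degenerate` attribute when only one
#'   class is present.
#' @export
auc_roc <- function(probs, labels) {
  stopifnot(length(probs) == length(labels))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    return(structure(0, degenerate = TRUE))
  ord <- order(probs, decreasing = TRUE)
  p <- probs[ord]; y <- labels[ord]
  # cumulative TP/FP after each distinct-threshold block
  block_last <- c(which(diff(p) != 0), length(p))
  tp <- cumsum(y == 1)[block_last]
  fp <- cumsum(y == 0)[block_last]
  tpr <- c(0, tp / npos); fpr <- c(0, fp / nneg)
  sum((fpr[-1] - fpr[-length(fpr)]) *
      (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Compute the six evaluation metrics
#'
#' Accuracy, balanced accuracy, precision, recall, F-score (2TP /
#' (2TP + FP + FN)) and, when scores are supplied, AUC.  Metrics whose
#' denominator is zero are reported as 0 and flagged in the
#' `zero_denominator` field.
#'
#' @param counts A `confusion_counts` object (or the result of calling
#'   [confusion()] on `calls`/`labels`).
#' @param probs Optional numeric scores for AUC.
#' @param labels Optional binary labels (required with `probs`).
#' @return A `metrics_report`: list with fields accuracy,
#'   balanced_accuracy, precision, recall, fscore, auc, counts,
#'   zero_denominator.
#' @export
compute_metrics <- function(counts, probs = NULL, labels = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  if (tp + tn + fp + fn < 1) stop("empty confusion counts")
  flags <- character(0)
  if (tp + fp == 0) flags <- c(flags, "precision")
  if (tp + fn == 0) flags <- c(flags, "recall")
  acc <- (tp + tn) / (tp + tn + fp + fn)
  bacc <- (.safe_div(tp, tp + fn) + .safe_div(tn, tn + fp)) / 2
  precision <- .safe_div(tp, tp + fp)
  recall <- .safe_div(tp, tp + fn)
  fscore <- .safe_div(2 * tp, 2 * tp + fp + fn)
  auc <- NA_real_
  if (!is.null(probs)) {
    if (is.null(labels)) stop("labels required to compute AUC")
    auc <- as.numeric(auc_roc(probs, labels))
  }
  structure(list(accuracy = acc, balanced_accuracy = bacc,
                 precision = precision, recall = recall, fscore = fscore,
                 auc = auc, counts = counts, zero_denominator = flags),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  vals <- c(Acc = x$accuracy, BAcc = x$balanced_accuracy,
            Precision = x$precision, Recall = x$recall,
            FScore = x$fscore, AUC = x$auc)
  cat(paste(sprintf("%-9s", names(vals)), collapse = " "), "\n")
  cat(paste(sprintf("%-9s", ifelse(is.na(vals), "-",
                                   formatC(vals, digits = digits,
                                           format = "f"))),
            collapse = " "), "\n")
  if (length(x$zero_denominator))
    cat("zero-denominator metric(s) reported as 0: ",
        paste(x$zero_denominator, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Serialize a metrics report to JSON
#' @param x A `metrics_report`.
#' @param path Optional output path; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
metrics_to_json <- function(x, path = NULL) {
  obj <- list(accuracy = x$accuracy, balanced_accuracy = x$balanced_accuracy,
              precision = x$precision, recall = x$recall,
              fscore = x$fscore, auc = x$auc,
              counts = unclass(x$counts),
              zero_denominator = as.list(x$zero_denominator))
  if (is.null(path))
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                         digits = NA, null = "null")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
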