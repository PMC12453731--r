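# Confusion-matrix metrics, ROC/AUC, model evaluation and the
# missing-modality protocol.  Positive class = abnormal = 1 throughout.

#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred Equal-length vectors of labels in {0, 1}
#'   (1 = abnormal = positive class).
#' @return Named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion <- function(y_true, y_pred) {
  if (!length(y_true) || length(y_true) != length(y_pred))
    stop("y_true and y_pred must be nonempty and of equal length")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    stop("labels must be in {0, 1}")
  c(tp = sum(y_true == 1 & y_pred == 1),
    fp = sum(y_true == 0 & y_pred == 1),
    tn = sum(y_true == 0 & y_pred == 0),
    fn = sum(y_true == 1 & y_pred == 0))
}

#' Metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, false-positive rate `FP/(FP+TN)`, precision `TP/(TP+FP)`
#' and F1 `2TP/(2TP+FP+FN)`. A metric whose denominator is zero is returned
#' as `NA` (flagged undefined, never silently 0).
#'
#' @param tp,fp,tn,fn Non-negative confusion counts (total > 0).
#' @return One-row tibble: counts plus the six metric columns.
#' @export
metrics_from_confusion <- function(tp, fp, tn, fn) {
  total <- tp + fp + tn + fn
  if (total <= 0) stop("metrics undefined: all confusion counts are zero")
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / total,
    sensitivity = frac(tp, tp + fn),
    specificity = frac(tn, tn + fp),
    fpr = frac(fp, fp + tn),
    precision = frac(tp, tp + fp),
    f1 = frac(2 * tp, 2 * tp + fp + fn))
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores with trapezoidal area. Tied scores
#' enter the curve as a single operating point, which makes the area equal
#' to the rank-averaged (Mann-Whitney) statistic.
#'
#' @param y_true Labels in {0, 1}; both classes must be present.
#' @param scores Positive-class (abnormal) probabilities or scores.
#' @return A `cf_roc` list: `auc` and a `curve` tibble (threshold, fpr,
#'   tpr).
#' @export
roc_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores))
    stop("y_true and scores must have equal length")
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC undefined: one class is absent")
  ord <- order(scores, decreasing = TRUE)
  ys <- y_true[ord]
  ss <- scores[ord]
  grp <- cumsum(!duplicated(ss))             # tie groups in score order
  tp <- cumsum(ys == 1)
  fp <- cumsum(ys == 0)
  last <- which(grp != c(grp[-1], -1))       # last index of each tie group
  curve <- tibble::tibble(
    threshold = c(Inf, ss[last]),
    tpr = c(0, tp[last] / n_pos),
    fpr = c(0, fp[last] / n_neg))
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
  structure(list(auc = auc, curve = curve), class = "cf_roc")
}

#' @export
print.cf_roc <- function(x, ...) {
  cat("<cf_roc> AUC =", sprintf("%.4f", x$auc), "with",
      nrow(x$curve), "operating points\n")
  invisible(x)
}

#' Evaluate a model on a segment subset
#'
#' Scores the requested segments, thresholds the abnormal-class probability
#' at `threshold`, and reports confusion counts, the derived metrics and the
#' AUC (when both classes are present).
#'
#' @param model A `cf_model`.
#' @param dataset A `segment_dataset`.
#' @param idx Segment indices to evaluate (default: all).
#' @param drop Modality to zero at inference (missing-modality protocol):
#'   `"none"`, `"ecg"` or `"pcg"`.
#' @param threshold Decision threshold on P(abnormal).
#' @param batch Evaluation batch size.
#' @return One-row metrics tibble (counts, metrics, `auc`, `n`).
#' @export
evaluate_model <- function(model, dataset, idx = NULL, drop = "none",
                           threshold = 0.5, batch = 128L) {
  if (is.null(idx)) idx <- seq_len(nrow(dataset$meta))
  p <- predict_proba(model, dataset, idx, drop = drop, batch = batch)
  y <- dataset$meta$label[idx]
  cm <- confusion(y, as.integer(p >= threshold))
  met <- metrics_from_confusion(cm[["tp"]], cm[["fp"]], cm[["tn"]], cm[["fn"]])
  met$auc <- if (length(unique(y)) == 2) roc_auc(y, p)$auc else NA_real_
  met$n <- length(idx)
  met
}

#' Missing-modality evaluation
#'
#' Implements the missing-modality protocol: the dropped modality's input
#' values are set to zero for every segment while the present modality is
#' unchanged, and the model is evaluated as usual. `drop = "none"` is plain
#' evaluation. Requesting a drop on a single-modality variant is an error.
#'
#' @inheritParams evaluate_model
#' @param drop `"none"`, `"ecg"` or `"pcg"`.
#' @return One-row metrics tibble.
#' @export
evaluate_missing_modality <- function(model, dataset, idx = NULL,
                                      drop = c("none", "ecg", "pcg"),
                                      threshold = 0.5, batch = 128L) {
  drop <- match.arg(drop)
  evaluate_model(model, dataset, idx, drop = drop, threshold = threshold,
                 batch = batch)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-fold cross-validation metrics
#' @param x A `cf_cv` object.
#' @param ... Unused.
#' @return Tibble with one row per fold.
#' @export
tidy.cf_cv <- function(x, ...) x$per_fold

#' One-row cross-validation summary
#'
#' Fold-averaged metrics (mean and sd of accuracy) plus the pooled-confusion
#' accuracy.
#'
#' @param x A `cf_cv` object.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.cf_cv <- function(x, ...) {
  pf <- x$per_fold
  tibble::tibble(
    variant = x$variant, n_folds = nrow(pf),
    accuracy = mean(pf$accuracy), accuracy_sd = stats::sd(pf$accuracy),
    sensitivity = mean(pf$sensitivity), specificity = mean(pf$specificity),
    precision = mean(pf$precision), f1 = mean(pf$f1), auc = mean(pf$auc),
    pooled_accuracy = x$pooled$accuracy)
}

#' Tidy a trained model's history
#' @param x A trained `cf_model`.
#' @param ... Unused.
#' @return The history tibble (epoch, loss, lr).
#' @export
tidy.cf_model <- function(x, ...) train_history(x)

#' One-row model summary
#' @param x A `cf_model`.
#' @param ... Unused.
#' @return One-row tibble (variant, parameters, epochs trained, stop
#'   reason).
#' @export
glance.cf_model <- function(x, ...) {
  h <- train_history(x)
  tibble::tibble(variant = x$variant, n_params = cf_n_params(x),
                 epochs = if (is.null(h)) 0L else nrow(h),
                 final_loss = if (is.null(h)) NA_real_ else h$loss[nrow(h)],
                 stop_reason = if (is.null(h)) NA_character_
                               else attr(h, "stop_reason"))
}
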