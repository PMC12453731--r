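# ggplot2 presentation methods.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a synchronized record
#'
#' ECG and PCG channels as stacked facets with the S1 onset annotations
#' marked.
#'
#' @param object A `sync_record`.
#' @param window Optional numeric `c(from, to)` window in seconds.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sync_record <- function(object, window = NULL, ...) {
  df <- tibble::tibble(
    time = rep(seq_along(object$ecg) - 1, 2) / object$fs,
    value = c(object$ecg, object$pcg),
    channel = rep(c("ECG", "PCG"), each = length(object$ecg)))
  s1 <- tibble::tibble(time = object$s1_onsets / object$fs)
  if (!is.null(window)) {
    df <- dplyr::filter(df, .data$time >= window[1], .data$time <= window[2])
    s1 <- dplyr::filter(s1, .data$time >= window[1], .data$time <= window[2])
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(data = s1, ggplot2::aes(xintercept = .data$time),
                        colour = "red", linetype = "dashed", alpha = 0.6) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = paste0(object$record_id, " (S1 onsets dashed)")) +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#' @param object A `cf_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cf_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.4f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#' @param object A `cf_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cf_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$per_fold,
    c("accuracy", "sensitivity", "specificity", "precision", "f1"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$fold)), size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::labs(title = paste("Cross-validation:", object$variant),
                  colour = "fold", y = NULL, x = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a training history
#' @param model A trained `cf_model`.
#' @return A ggplot of loss and learning rate per epoch.
#' @export
plot_history <- function(model) {
  h <- train_history(model)
  if (is.null(h)) stop("model has no training history")
  long <- tidyr::pivot_longer(h, c("loss", "lr"), names_to = "series")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' 2x2 tile rendering of a metrics row's confusion counts.
#'
#' @param metrics One-row metrics tibble from [evaluate_model()] or
#'   [metrics_from_confusion()].
#' @return A ggplot.
#' @export
plot_confusion <- function(metrics) {
  df <- tibble::tibble(
    truth = factor(c("abnormal", "normal", "normal", "abnormal"),
                   levels = c("normal", "abnormal")),
    predicted = factor(c("abnormal", "abnormal", "normal", "normal"),
                       levels = c("normal", "abnormal")),
    count = c(metrics$tp, metrics$fp, metrics$tn, metrics$fn))
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_fill_gradient(low = "grey40", high = "firebrick") +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = sprintf("accuracy %.3f", metrics$accuracy))
}
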