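# Plotting helpers beyond the autoplot() methods defined with each class.

#' ROC and precision-recall point sets
#'
#' `roc_points()` returns the (FPR, TPR) staircase; `pr_points()` the
#' (recall, precision) points at each unique score threshold (descending),
#' matching the step-wise conventions of [roc_auc()] / [pr_auc()].
#'
#' @param score Finite numeric scores.
#' @param label 0/1 labels, both classes present.
#' @return A tibble of curve points.
#' @export
roc_points <- function(score, label) {
  check_binary_metric_input(score, label)
  p <- sum(label == 1L)
  q <- sum(label == 0L)
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  pos <- as.integer(label[ord] == 1L)
  last <- which(!duplicated(s, fromLast = TRUE))
  tibble(
    threshold = s[last],
    tpr = cumsum(pos)[last] / p,
    fpr = (seq_along(s)[last] - cumsum(pos)[last]) / q
  ) |>
    (\(d) dplyr::bind_rows(tibble(threshold = Inf, tpr = 0, fpr = 0), d))()
}

#' @rdname roc_points
#' @export
pr_points <- function(score, label) {
  check_binary_metric_input(score, label)
  p <- sum(label == 1L)
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  pos <- as.integer(label[ord] == 1L)
  last <- which(!duplicated(s, fromLast = TRUE))
  tibble(
    threshold = s[last],
    recall = cumsum(pos)[last] / p,
    precision = cumsum(pos)[last] / seq_along(s)[last]
  )
}

#' Screening z-score overview plot
#'
#' Histogram of per-feature Mann-Whitney z-scores by block with the cutoff
#' marked; features right of the line are kept.
#'
#' @param object A `feature_screen` from [screen_features()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot feature_screen
#' @export
autoplot.feature_screen <- function(object, ...) {
  df <- dplyr::filter(object$z_table, .data$screened)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z1, fill = .data$block)) +
    ggplot2::geom_histogram(bins = 60, position = "identity", alpha = 0.6) +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = "dashed") +
    ggplot2::labs(x = "Mann-Whitney z (positive = Mendelian-enriched)",
                  y = "features",
                  title = sprintf("Feature screening at z > %g",
                                  object$cutoff))
}
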