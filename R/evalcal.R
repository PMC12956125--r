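#' Empirical precision calibration curve
#'
#' Converts raw regression scores to predicted precision: for each observed
#' score threshold `S0`, the fraction of known positives among all genes
#' whose raw score is at least `S0`. The inclusive "at least" variant is
#' used so that every gene, including the top-ranked one, has a defined
#' predicted precision; at the minimal threshold the precision equals the
#' overall prevalence P/N.
#'
#' @param data Data frame with columns `score` (finite numeric) and `label`
#'   (0/1); typically a prediction table joined with labels.
#' @return A `calibration_curve` tibble with columns `threshold` (ascending
#'   unique scores), `n_above` (genes with score >= threshold),
#'   `n_pos_above`, and `precision`.
#' @export
calibration_curve <- function(data) {
  if (!all(c("score", "label") %in% names(data))) {
    abort("`data` needs columns `score` and `label`.")
  }
  if (any(!is.finite(data$score))) abort("scores must be finite.")
  if (sum(data$label == 1L) == 0L) {
    abort("calibration needs at least one positive gene.")
  }
  ord <- order(data$score, decreasing = TRUE)
  s <- data$score[ord]
  pos <- as.integer(data$label[ord] == 1L)
  cum_n <- seq_along(s)
  cum_pos <- cumsum(pos)
  # last index of each tied run = counts inclusive of the whole tie group
  last <- which(!duplicated(s, fromLast = TRUE))
  curve <- tibble(
    threshold = rev(s[last]),
    n_above = rev(cum_n[last]),
    n_pos_above = rev(cum_pos[last])
  )
  curve$precision <- curve$n_pos_above / curve$n_above
  class(curve) <- c("calibration_curve", class(curve))
  curve
}

#' Predicted precision at given raw scores
#'
#' Step-wise lookup on a calibration curve: a score maps to the precision of
#' the largest threshold not exceeding it; scores below every threshold map
#' to the overall prevalence (the precision of the lowest threshold).
#'
#' @param curve A [calibration_curve()].
#' @param scores Numeric vector of raw scores.
#' @return Numeric vector of predicted precisions in `[0, 1]`.
#' @export
precision_at <- function(curve, scores) {
  stopifnot(inherits(curve, "calibration_curve"))
  idx <- findInterval(scores, curve$threshold)
  idx[idx == 0L] <- 1L
  curve$precision[idx]
}

#' Ranking metrics: AUC and area under the precision-recall curve
#'
#' `roc_auc()` is the probability that a uniformly random positive outranks
#' a uniformly random negative, with ties counted half — the rank-statistic
#' form equivalent to the trapezoidal ROC area. `pr_auc()` is the step-wise
#' precision-recall area (average precision): no linear interpolation
#' between PR points, with tied scores handled as one block.
#'
#' @param score Finite numeric scores (higher = more Mendelian-like).
#' @param label 0/1 labels; both classes must be present.
#' @return A single number in `[0, 1]`.
#' @export
roc_auc <- function(score, label) {
  check_binary_metric_input(score, label)
  pos <- label == 1L
  p <- sum(pos)
  q <- sum(!pos)
  r <- rank(score, ties.method = "average")
  (sum(r[pos]) - p * (p + 1) / 2) / (p * q)
}

#' @rdname roc_auc
#' @export
pr_auc <- function(score, label) {
  check_binary_metric_input(score, label)
  p <- sum(label == 1L)
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  pos <- as.integer(label[ord] == 1L)
  last <- which(!duplicated(s, fromLast = TRUE)) # end of each tied block
  tp <- cumsum(pos)[last]
  n_above <- seq_along(s)[last]
  precision <- tp / n_above
  recall <- tp / p
  sum(diff(c(0, recall)) * precision)
}

check_binary_metric_input <- function(score, label) {
  if (length(score) != length(label)) {
    abort("`score` and `label` must have the same length.")
  }
  if (any(!is.finite(score))) abort("scores must be finite.")
  if (!all(label %in% c(0L, 1L))) abort("labels must be 0/1.")
  if (length(unique(label)) < 2L) {
    abort("both classes must be present to compute a ranking metric.")
  }
  invisible(NULL)
}

#' Top-k enrichment factor
#'
#' The fraction of positives among the `k` top-ranked genes divided by the
#' overall prevalence `p/n`. Ranking is by descending score with ties broken
#' by ascending `gene_id` so reports are reproducible. Its ceiling,
#' `max_enrichment()`, is attained when every top-k gene is positive:
#' `(min(k, p) / k) / (p / n)`.
#'
#' @param data Data frame with columns `gene_id`, `score`, `label`.
#' @param k Number of top-ranked genes to consider (`1 <= k <= n`).
#' @return A single enrichment factor (fold over prevalence).
#' @export
enrichment_factor <- function(data, k) {
  if (!all(c("gene_id", "score", "label") %in% names(data))) {
    abort("`data` needs columns `gene_id`, `score`, `label`.")
  }
  n <- nrow(data)
  p <- sum(data$label == 1L)
  if (p == 0L) abort("enrichment is undefined with no positives.")
  if (k < 1L || k > n) abort("`k` must be between 1 and the number of genes.")
  ord <- order(-data$score, data$gene_id)
  top <- data$label[ord][seq_len(k)]
  (sum(top == 1L) / k) / (p / n)
}

#' @rdname enrichment_factor
#' @param n Total number of genes.
#' @param p Number of positives (`p >= 1`).
#' @export
max_enrichment <- function(n, p, k) {
  if (p < 1L) abort("enrichment is undefined with no positives.")
  if (k < 1L || k > n) abort("`k` must be between 1 and `n`.")
  (min(k, p) / k) / (p / n)
}

#' One-row evaluation report
#'
#' @param data Data frame with columns `gene_id`, `score`, `label`.
#' @param k Top-k for the enrichment factor.
#' @return Tibble with `auc`, `aupr`, `ef_at_k`, `max_ef_at_k`, `k`, `n`,
#'   `p`.
#' @export
eval_report <- function(data, k = 180L) {
  n <- nrow(data)
  p <- sum(data$label == 1L)
  k <- min(k, n)
  tibble(
    auc = roc_auc(data$score, data$label),
    aupr = pr_auc(data$score, data$label),
    ef_at_k = enrichment_factor(data, k),
    max_ef_at_k = max_enrichment(n, p, k),
    k = as.integer(k), n = n, p = p
  )
}

#' Plot a calibration curve
#'
#' @param object A [calibration_curve()].
#' @param ... Unused.
#' @return A ggplot: predicted precision as a step function of the raw
#'   score threshold.
#' @method autoplot calibration_curve
#' @export
autoplot.calibration_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$threshold, y = .data$precision)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "raw score threshold",
                  y = "empirical precision (inclusive)",
                  title = "Score-to-precision calibration") +
    ggplot2::ylim(0, 1)
}
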