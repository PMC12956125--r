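#' Run the full prioritization pipeline
#'
#' End-to-end procedure: (1) Mann-Whitney screening of the pathway and GO
#' membership blocks at `cutoff` on the full labelled set; (2) round-one
#' 10-fold out-of-fold predictions with regression targets 1.0 (Mendelian) /
#' 0.0 (unknown); (3) optionally, an iterated round: the composite round-one
#' scores are calibrated to empirical precision and unknowns are retrained
#' against their predicted precision, reusing the same fold assignment so
#' the rounds are comparable gene-by-gene.
#'
#' @param fm Feature matrix from [assemble_features()].
#' @param labels Gene label table (`gene_id`, `label`).
#' @param config A [boost_config()].
#' @param cutoff Screening z-score cutoff (strict; default 0.1).
#' @param k_folds Number of cross-validation folds (default 10).
#' @param iterate Run the precision-relabel second round (default `TRUE`).
#' @param top_k Top-k for the reported enrichment factor (default 180).
#' @param seed Integer seed for the fold assignment (the boosting backend
#'   uses `config$seed`).
#' @param screen_blocks Blocks subject to screening.
#' @return A `mendel_fit` with elements `predictions` (tibble: `gene_id`,
#'   `label`, `raw_score`, `predicted_precision`, `rank`), `metrics` (one
#'   row per round), `screen`, `curve` (final calibration), `curve_round1`,
#'   `round1`, `folds`, `config`, plus the call parameters. `tidy()` returns
#'   the predictions, `glance()` the final-round metrics.
#' @export
mendel_rank <- function(fm, labels, config = boost_config(), cutoff = 0.1,
                        k_folds = 10L, iterate = TRUE, top_k = 180L,
                        seed = 1L,
                        screen_blocks = c("pathway", "go_process")) {
  labels <- align_labels(labels, fm$gene_ids)
  screen <- screen_features(fm, labels, cutoff = cutoff,
                            screen_blocks = screen_blocks)
  folds <- make_folds(labels, k = k_folds, seed = seed)

  targets1 <- tibble(gene_id = labels$gene_id,
                     target = as.numeric(labels$label))
  round1 <- cross_val_predict(screen$matrix, targets1, folds, config)
  eval1 <- with_labels(round1, labels)
  curve1 <- calibration_curve(eval1)

  if (iterate) {
    targets2 <- iterate_targets(round1, labels, curve1)
    round2 <- cross_val_predict(screen$matrix, targets2, folds, config)
    final <- round2
  } else {
    final <- round1
  }
  eval_final <- with_labels(final, labels)
  curve <- calibration_curve(eval_final)

  metrics <- dplyr::bind_rows(
    dplyr::mutate(eval_report(eval1, k = top_k), round = 1L,
                  .before = 1L),
    if (iterate) {
      dplyr::mutate(eval_report(eval_final, k = top_k), round = 2L,
                    .before = 1L)
    }
  )
  predictions <- eval_final |>
    dplyr::transmute(
      gene_id = .data$gene_id,
      label = .data$label,
      raw_score = .data$score,
      predicted_precision = precision_at(curve, .data$score)
    ) |>
    dplyr::arrange(-.data$raw_score, .data$gene_id) |>
    dplyr::mutate(rank = dplyr::row_number())

  structure(list(predictions = predictions, metrics = metrics,
                 screen = screen, curve = curve, curve_round1 = curve1,
                 round1 = round1, folds = folds, config = config,
                 cutoff = cutoff, iterate = iterate, top_k = top_k,
                 seed = seed),
            class = "mendel_fit")
}

with_labels <- function(pred, labels) {
  pred |>
    dplyr::transmute(gene_id = .data$gene_id, score = .data$score) |>
    dplyr::left_join(labels[, c("gene_id", "label")], by = "gene_id")
}

#' @export
print.mendel_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<mendel_fit> %d genes (%d positive), %s\n",
    g$n, g$p, if (x$iterate) "iterated (2 rounds)" else "single round"))
  cat(sprintf("  AUC %.3f | AUPR %.3f | EF@%d %.2f (max %.2f)\n",
              g$auc, g$aupr, g$k, g$ef_at_k, g$max_ef_at_k))
  invisible(x)
}

#' @describeIn mendel_rank Per-gene prediction table.
#' @param x A `mendel_fit`.
#' @param ... Unused.
#' @method tidy mendel_fit
#' @export
tidy.mendel_fit <- function(x, ...) x$predictions

#' @describeIn mendel_rank One-row final metrics
#'   (`auc`, `aupr`, `ef_at_k`, `max_ef_at_k`, `k`, `n`, `p`).
#' @method glance mendel_fit
#' @export
glance.mendel_fit <- function(x, ...) {
  dplyr::select(x$metrics[nrow(x$metrics), ], -"round")
}

#' @describeIn mendel_rank Ranked-score plot coloured by label with the
#'   predicted-precision overlay.
#' @param object A `mendel_fit`.
#' @method autoplot mendel_fit
#' @export
autoplot.mendel_fit <- function(object, ...) {
  df <- object$predictions
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$raw_score,
                                     colour = factor(.data$label)),
                        size = 0.4, alpha = 0.6) +
    ggplot2::geom_step(ggplot2::aes(y = .data$predicted_precision),
                       colour = "black") +
    ggplot2::scale_colour_manual(values = c(`0` = "grey60", `1` = "firebrick"),
                                 name = "label") +
    ggplot2::labs(x = "rank", y = "raw score / predicted precision",
                  title = "Composite out-of-fold predictions")
}

#' Candidate report
#'
#' Genes whose predicted precision meets the cutoff, sorted by descending
#' raw score — the novel-candidate list when restricted to unknowns.
#'
#' @param fit A `mendel_fit` (or its `tidy()` prediction tibble).
#' @param min_precision Predicted-precision cutoff (default 0.7).
#' @param novel_only Keep only unknown (label 0) genes (default `TRUE`).
#' @return Tibble of candidate genes.
#' @export
report_candidates <- function(fit, min_precision = 0.7, novel_only = TRUE) {
  pred <- if (inherits(fit, "mendel_fit")) fit$predictions else fit
  out <- dplyr::filter(pred, .data$predicted_precision >= min_precision)
  if (novel_only) out <- dplyr::filter(out, .data$label == 0L)
  dplyr::arrange(out, -.data$raw_score, .data$gene_id)
}
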