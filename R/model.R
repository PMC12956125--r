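#' Boosted-regression configuration
#'
#' Hyperparameters of the gradient-boosted regression-tree scorer. The
#' defaults are the pipeline's standard operating point: 1000 trees of
#' depth 6 with learning rate 0.05 under squared-error loss.
#'
#' @param n_estimators Number of boosting rounds (>= 1).
#' @param max_depth Maximum tree depth.
#' @param learning_rate Shrinkage (> 0).
#' @param seed Integer seed controlling any backend randomness.
#' @param nthread Threads for the backend; 1 keeps fits bit-reproducible.
#' @return A `boost_config` list.
#' @export
boost_config <- function(n_estimators = 1000L, max_depth = 6L,
                         learning_rate = 0.05, seed = 1L, nthread = 1L) {
  if (n_estimators < 1L) abort("`n_estimators` must be >= 1.")
  if (learning_rate <= 0) abort("`learning_rate` must be > 0.")
  structure(list(n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 learning_rate = learning_rate,
                 loss = "squared_error",
                 seed = as.integer(seed),
                 nthread = as.integer(nthread)),
            class = "boost_config")
}

#' Balanced random fold assignment
#'
#' Randomly partitions genes into `k` folds whose sizes differ by at most
#' one; deterministic given the seed.
#'
#' @param genes Data frame with a `gene_id` column (and usually `label`).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Tibble with `gene_id` and `fold` (0-based fold index).
#' @export
make_folds <- function(genes, k = 10L, seed = 1L) {
  gene_ids <- as.character(genes$gene_id)
  n <- length(gene_ids)
  if (n < k) abort(sprintf("need at least %d genes for %d folds.", k, k))
  perm <- with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k) - 1L, length.out = n)
  tibble(gene_id = gene_ids, fold = fold)
}

#' Fit the gradient-boosted regression scorer
#'
#' Fits boosted regression trees with squared-error loss on a gene-by-feature
#' matrix against regression targets in `[0, 1]` (1.0 for known Mendelian
#' genes). The ensemble is initialised at the mean target, and single-thread
#' histogram growth makes fits deterministic for a fixed config.
#'
#' @param x Numeric feature matrix (genes x features), or a feature matrix
#'   from [assemble_features()].
#' @param y Numeric target vector aligned with rows of `x`.
#' @param config A [boost_config()].
#' @return A `boost_fit`; use `predict(fit, x)` for raw scores.
#' @export
fit_boost <- function(x, y, config = boost_config()) {
  if (inherits(x, "feature_matrix")) x <- x$values
  x <- as.matrix(x)
  if (any(!is.finite(x))) abort("features must be finite (no NA/NaN).")
  if (any(!is.finite(y))) abort("targets must be finite (no NA/NaN).")
  if (nrow(x) != length(y)) abort("`x` rows and `y` length must match.")
  params <- list(
    objective = "reg:squarederror",
    max_depth = config$max_depth,
    eta = config$learning_rate,
    nthread = config$nthread,
    tree_method = "hist",
    base_score = mean(y),
    seed = config$seed
  )
  booster <- xgboost::xgb.train(
    params = params,
    data = xgboost::xgb.DMatrix(x, label = y, nthread = config$nthread),
    nrounds = config$n_estimators,
    verbose = 0
  )
  structure(list(booster = booster, config = config,
                 feature_names = colnames(x)),
            class = "boost_fit")
}

#' @export
predict.boost_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names) &&
      !identical(colnames(newdata), object$feature_names)) {
    abort("`newdata` columns do not match the training features.")
  }
  as.numeric(predict(object$booster,
                     xgboost::xgb.DMatrix(newdata,
                                          nthread = object$config$nthread)))
}

#' Out-of-fold cross-validated predictions
#'
#' Trains one scorer per fold on the other folds and scores the held-out
#' genes, then combines the held-out predictions into one composite set
#' with exactly one score per gene.
#'
#' @param fm Feature matrix (or plain matrix with rownames = gene ids).
#' @param targets Data frame with `gene_id` and `target` columns.
#' @param folds Fold assignment from [make_folds()].
#' @param config A [boost_config()].
#' @return Tibble with `gene_id`, `fold`, `score`.
#' @export
cross_val_predict <- function(fm, targets, folds, config = boost_config()) {
  x <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  gene_ids <- rownames(x)
  if (is.null(gene_ids)) abort("feature rows must be named by gene id.")
  if (!setequal(folds$gene_id, gene_ids)) {
    abort("fold assignment does not cover the feature matrix genes.")
  }
  y <- targets$target[match(gene_ids, targets$gene_id)]
  if (any(is.na(y))) abort("every gene needs a target value.")
  fold_of <- folds$fold[match(gene_ids, folds$gene_id)]
  out <- vector("list", length(unique(fold_of)))
  for (f in sort(unique(fold_of))) {
    test <- fold_of == f
    y_train <- y[!test]
    if (all(y_train == y_train[[1]])) {
      warn(sprintf("fold %d: training targets are constant.", f))
    }
    fit <- fit_boost(x[!test, , drop = FALSE], y_train, config)
    out[[f + 1L]] <- tibble(gene_id = gene_ids[test], fold = f,
                            score = predict(fit, x[test, , drop = FALSE]))
  }
  dplyr::arrange(dplyr::bind_rows(out),
                 match(.data$gene_id, gene_ids))
}

#' Precision-relabelled targets for the iterated training round
#'
#' Known positives keep a regression target of 1.0. Each unknown gene's
#' target is replaced by its empirical predicted precision under the
#' round-one composite out-of-fold scores, so unknowns that rank among the
#' positives are no longer forced to 0.
#'
#' @param round1 Prediction tibble (`gene_id`, `score`) from
#'   [cross_val_predict()].
#' @param labels Gene label table.
#' @param curve [calibration_curve()] built from the same round-one scores
#'   and labels.
#' @return Tibble with `gene_id`, `target` in `[0, 1]`.
#' @export
iterate_targets <- function(round1, labels, curve) {
  check_gene_table(labels)
  idx <- match(labels$gene_id, round1$gene_id)
  if (any(is.na(idx))) {
    abort("every labelled gene needs a round-one prediction.")
  }
  score <- round1$score[idx]
  tibble(
    gene_id = labels$gene_id,
    target = ifelse(labels$label == 1L, 1.0, precision_at(curve, score))
  )
}
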