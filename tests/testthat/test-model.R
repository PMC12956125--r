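test_that("fold assignment is balanced, exhaustive, deterministic, and guarded", {
  genes <- tibble::tibble(gene_id = sprintf("G%05d", 1:20), label = 0L)
  f <- make_folds(genes, k = 10, seed = 3)
  expect_equal(sort(unique(f$fold)), 0:9)
  expect_true(all(table(f$fold) == 2))
  expect_identical(f, make_folds(genes, k = 10, seed = 3))
  expect_false(identical(f$fold, make_folds(genes, k = 10, seed = 4)$fold))

  big <- tibble::tibble(gene_id = sprintf("G%05d", 1:17858), label = 0L)
  sizes <- as.integer(table(make_folds(big, k = 10, seed = 1)$fold))
  expect_true(all(sizes %in% c(1785L, 1786L)))
  expect_equal(sum(sizes), 17858L)

  expect_error(make_folds(genes[1:9, ], k = 10), "at least")
})

test_that("the boosted regressor reproduces a constant target and rejects NaN", {
  x <- matrix(rnorm(60), 20, 3, dimnames = list(sprintf("G%d", 1:20), NULL))
  fit <- fit_boost(x, rep(0.37, 20), fast_config())
  expect_equal(predict(fit, x), rep(0.37, 20), tolerance = 1e-6)
  expect_error(fit_boost(cbind(x, NA), rep(0.5, 20), fast_config()), "finite")
  expect_error(fit_boost(x, c(rep(0.5, 19), NaN), fast_config()), "finite")
})

test_that("training error does not exceed the constant-mean predictor's", {
  withr::with_seed(40, {
    x <- matrix(rnorm(200), 50, 4)
    y <- as.numeric(x[, 1] > 0)
  })
  fit <- fit_boost(x, y, fast_config())
  pred <- predict(fit, x)
  expect_lte(mean((pred - y)^2), mean((mean(y) - y)^2))
})

test_that("a perfectly separating 1-D feature yields a matching predicted ranking", {
  x <- matrix(seq_len(60), ncol = 1, dimnames = list(sprintf("G%02d", 1:60),
                                                     "f"))
  y <- as.numeric(seq_len(60) > 30)
  fit <- fit_boost(x, y, fast_config())
  pred <- predict(fit, x)
  expect_equal(roc_auc(pred, y), 1.0)
})

test_that("cross-validation produces one out-of-fold score per gene", {
  b <- tiny_bundle(seed = 41L)
  fm <- bundle_features(b)
  folds <- make_folds(b$labels, k = 5, seed = 2)
  targets <- tibble::tibble(gene_id = b$labels$gene_id,
                            target = as.numeric(b$labels$label))
  pred <- cross_val_predict(fm, targets, folds, fast_config())
  expect_equal(sort(pred$gene_id), sort(b$labels$gene_id))
  expect_equal(anyDuplicated(pred$gene_id), 0L)
  expect_true(all(is.finite(pred$score)))
  # each gene was scored by the model of its own fold
  expect_equal(pred$fold,
               folds$fold[match(pred$gene_id, folds$gene_id)])
})

test_that("a fold stripped of positives warns but still yields predictions", {
  withr::with_seed(42, {
    x <- matrix(rnorm(40 * 3), 40, 3,
                dimnames = list(sprintf("G%02d", 1:40), NULL))
  })
  labels <- tibble::tibble(gene_id = rownames(x),
                           label = c(rep(1L, 4), rep(0L, 36)))
  # all positives sit in fold 1, so fold 1's training set has none
  folds <- tibble::tibble(gene_id = rownames(x),
                          fold = c(rep(1L, 4), rep(0:1, 18)))
  targets <- tibble::tibble(gene_id = labels$gene_id,
                            target = as.numeric(labels$label))
  expect_warning(pred <- cross_val_predict(x, targets, folds, fast_config()),
                 "constant")
  expect_equal(nrow(pred), 40L)
})

test_that("iterated targets follow the worked three-gene example and its bounds", {
  round1 <- tibble::tibble(gene_id = c("A", "B", "C"),
                           score = c(0.9, 0.4, 0.3))
  labels <- tibble::tibble(gene_id = c("A", "B", "C"),
                           label = c(1L, 0L, 0L))
  curve <- calibration_curve(tibble::tibble(score = round1$score,
                                            label = labels$label))
  tg <- iterate_targets(round1, labels, curve)
  expect_equal(tg$target, c(1.0, 1 / 2, 1 / 3))
  # positives stay at exactly 1 regardless of their score
  all_pos <- iterate_targets(round1,
                             dplyr::mutate(labels, label = 1L),
                             calibration_curve(
                               tibble::tibble(score = round1$score, label = 1L)))
  expect_equal(all_pos$target, rep(1.0, 3))
  expect_error(iterate_targets(round1[1:2, ], labels, curve), "round-one")
})

test_that("an unknown outscoring all positives under a zero-precision curve gets target zero", {
  labels <- tibble::tibble(gene_id = c("U", "P"), label = c(0L, 1L))
  round1 <- tibble::tibble(gene_id = c("U", "P"), score = c(0.9, 0.1))
  curve <- calibration_curve(tibble::tibble(score = round1$score,
                                            label = labels$label))
  tg <- iterate_targets(round1, labels, curve)
  expect_equal(tg$target[tg$gene_id == "U"], 0.0)
  expect_equal(tg$target[tg$gene_id == "P"], 1.0)
})

test_that("round-two targets increase weakly with round-one score under a monotone curve", {
  withr::with_seed(43, {
    score <- sort(runif(40))
    label <- as.integer(runif(40) < score) # calibrated by construction
  })
  if (sum(label) == 0) label[40] <- 1L
  labels <- tibble::tibble(gene_id = sprintf("G%02d", 1:40), label = label)
  round1 <- tibble::tibble(gene_id = labels$gene_id, score = score)
  curve <- calibration_curve(tibble::tibble(score = score, label = label))
  if (all(diff(curve$precision) >= 0)) {
    tg <- iterate_targets(round1, labels, curve)
    unk <- tg$target[labels$label == 0L]
    expect_true(all(diff(unk[order(score[labels$label == 0L])]) >= -1e-12))
  }
  tg <- iterate_targets(round1, labels, curve)
  expect_true(all(tg$target >= 0 & tg$target <= 1))
})

test_that("the pipeline is deterministic, keeps positives at 1.0, and honours the iterate switch", {
  b <- tiny_bundle(seed = 44L)
  fm <- bundle_features(b)
  fit1 <- mendel_rank(fm, b$labels, config = fast_config(), k_folds = 5,
                      iterate = TRUE, top_k = 15, seed = 7)
  fit2 <- mendel_rank(fm, b$labels, config = fast_config(), k_folds = 5,
                      iterate = TRUE, top_k = 15, seed = 7)
  expect_identical(fit1$predictions, fit2$predictions)
  expect_equal(nrow(fit1$metrics), 2L)
  # the same folds are reused across rounds
  expect_identical(fit1$folds, fit2$folds)

  no_iter <- mendel_rank(fm, b$labels, config = fast_config(), k_folds = 5,
                         iterate = FALSE, top_k = 15, seed = 7)
  expect_equal(nrow(no_iter$metrics), 1L)
  # round one is unaffected by the iterate switch
  expect_equal(no_iter$predictions$raw_score[
    order(no_iter$predictions$gene_id)],
    fit1$round1$score[order(fit1$round1$gene_id)])
  # relabelled targets: positives exactly 1.0
  tg <- iterate_targets(fit1$round1, b$labels, fit1$curve_round1)
  expect_true(all(tg$target[b$labels$label == 1L] == 1.0))
  expect_true(all(tg$target >= 0 & tg$target <= 1))
})
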