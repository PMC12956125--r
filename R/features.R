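#' Feature blocks
#'
#' A feature block is a named gene-by-column numeric matrix, the unit from
#' which the full feature matrix is assembled. Blocks remember which genes
#' lacked source data (`flagged`), e.g. genes without an embedding row or
#' without any scored variant, which are zero-filled.
#'
#' @param name Block name, e.g. `"pathway"`, `"go_process"`, `"scores"`,
#'   `"embedding"`.
#' @param values Numeric matrix with one row per gene and column names set.
#' @param gene_ids Character vector of gene ids, one per row.
#' @param flagged Character vector of gene ids that were zero-filled for lack
#'   of data.
#' @return A `feature_block`.
#' @export
feature_block <- function(name, values, gene_ids, flagged = character()) {
  values <- as.matrix(values)
  if (ncol(values) == 0L) abort("a feature block must have at least 1 column.")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    abort("block columns must have unique names.")
  }
  if (nrow(values) != length(gene_ids)) {
    abort("`values` must have one row per gene id.")
  }
  if (!is.numeric(values) || any(!is.finite(values))) {
    abort("block values must be finite numerics.")
  }
  rownames(values) <- gene_ids
  structure(list(name = name, gene_ids = as.character(gene_ids),
                 values = values, flagged = as.character(flagged)),
            class = "feature_block")
}

#' @export
print.feature_block <- function(x, ...) {
  cat(sprintf("<feature_block> %s: %d genes x %d columns (%d zero-filled)\n",
              x$name, nrow(x$values), ncol(x$values), length(x$flagged)))
  invisible(x)
}

#' @export
dim.feature_block <- function(x) dim(x$values)

#' Binary membership block from a gene-set catalog
#'
#' One 0/1 column per term (1 if the gene belongs to the term) plus a
#' trailing count column holding the number of terms each gene belongs to,
#' so a catalog of `m` terms yields a block of width `m + 1`. Genes absent
#' from the catalog get an all-zero row.
#'
#' @param catalog A [term_catalog()].
#' @param genes Data frame with a `gene_id` column giving the row order.
#' @return A [feature_block()] named after the catalog namespace.
#' @export
membership_block <- function(catalog, genes) {
  stopifnot(inherits(catalog, "term_catalog"))
  gene_ids <- as.character(genes$gene_id)
  m <- matrix(0, nrow = length(gene_ids), ncol = length(catalog$terms),
              dimnames = list(gene_ids, names(catalog$terms)))
  for (j in seq_along(catalog$terms)) {
    m[gene_ids %in% catalog$terms[[j]], j] <- 1
  }
  counts <- rowSums(m)
  m <- cbind(m, counts)
  colnames(m)[ncol(m)] <- paste0(catalog$namespace, "_count")
  feature_block(catalog$namespace, m, gene_ids)
}

#' Aggregate a per-variant score table to one score per gene and kind
#'
#' The aggregate gene variation score is the arithmetic mean of a variant
#' pathogenicity predictor's scores over all scored variants of the gene of
#' the given kind (e.g. all possible missense substitutions, or a stop-gain
#' at every residue).
#'
#' @param scores Data frame with columns `gene_id`, `kind` (`"missense"` or
#'   `"nonsense"`) and `score`.
#' @param gene_id Single gene id.
#' @param kind Variant kind.
#' @return The mean score, or `NA_real_` when the gene/kind has no rows.
#' @export
aggregate_gene_score <- function(scores, gene_id, kind) {
  check_score_table(scores)
  s <- scores$score[scores$gene_id == gene_id & scores$kind == kind]
  if (length(s) == 0L) return(NA_real_)
  mean(s)
}

check_score_table <- function(scores) {
  if (!is.data.frame(scores) ||
      !all(c("gene_id", "kind", "score") %in% names(scores))) {
    abort("score table needs columns `gene_id`, `kind`, `score`.")
  }
  if (!all(scores$kind %in% c("missense", "nonsense"))) {
    abort("`kind` must be \"missense\" or \"nonsense\".")
  }
  if (any(!is.finite(scores$score))) abort("scores must be finite.")
  invisible(scores)
}

#' Two-column aggregate-score block
#'
#' Columns are `(missense_mean, nonsense_mean)` in that fixed order. Genes
#' with no scored variants of a kind get 0 for that column ("absent = no
#' evidence") and are flagged.
#'
#' @inheritParams aggregate_gene_score
#' @param genes Data frame with a `gene_id` column giving the row order.
#' @return A [feature_block()] named `"scores"`, width 2.
#' @export
score_block <- function(scores, genes) {
  check_score_table(scores)
  gene_ids <- as.character(genes$gene_id)
  agg <- scores |>
    dplyr::group_by(.data$gene_id, .data$kind) |>
    dplyr::summarise(mean_score = mean(.data$score), .groups = "drop")
  m <- matrix(0, nrow = length(gene_ids), ncol = 2L,
              dimnames = list(gene_ids, c("missense_mean", "nonsense_mean")))
  flagged <- character()
  for (k in c("missense", "nonsense")) {
    sub <- agg[agg$kind == k, ]
    idx <- match(gene_ids, sub$gene_id)
    col <- if (k == "missense") 1L else 2L
    m[!is.na(idx), col] <- sub$mean_score[idx[!is.na(idx)]]
    flagged <- union(flagged, gene_ids[is.na(idx)])
  }
  feature_block("scores", m, gene_ids, flagged = flagged)
}

#' Embedding block from a wide per-gene vector table
#'
#' @param embeddings Data frame whose first column is `gene_id` and whose
#'   remaining columns are the numeric embedding dimensions (fixed width).
#' @param genes Data frame with a `gene_id` column giving the row order.
#' @return A [feature_block()] named `"embedding"`; genes without an
#'   embedding row are zero-filled and flagged.
#' @export
embedding_block <- function(embeddings, genes) {
  if (!is.data.frame(embeddings) || names(embeddings)[[1]] != "gene_id") {
    abort("`embeddings` must be a data frame whose first column is `gene_id`.")
  }
  vals <- as.matrix(embeddings[, -1, drop = FALSE])
  if (!is.numeric(vals)) abort("embedding values must be numeric.")
  if (any(!is.finite(vals))) abort("embedding values must be finite.")
  gene_ids <- as.character(genes$gene_id)
  idx <- match(gene_ids, embeddings$gene_id)
  m <- matrix(0, nrow = length(gene_ids), ncol = ncol(vals),
              dimnames = list(gene_ids, colnames(vals)))
  m[!is.na(idx), ] <- vals[idx[!is.na(idx)], , drop = FALSE]
  feature_block("embedding", m, gene_ids, flagged = gene_ids[is.na(idx)])
}

#' Assemble feature blocks into one feature matrix
#'
#' Concatenates blocks column-wise, recording block boundaries so any block
#' can be sliced back out bit-exactly. All blocks must share the same gene
#' order; total width is the sum of block widths (e.g. 2 aggregate scores +
#' a 2,364-wide pathway block + a 12,536-wide GO block + 1,024 embedding
#' dimensions = 15,926 columns).
#'
#' @param ... [feature_block()] objects, or a single list of them.
#' @return A `feature_matrix`.
#' @export
assemble_features <- function(...) {
  blocks <- list(...)
  if (length(blocks) == 1L && !inherits(blocks[[1]], "feature_block")) {
    blocks <- blocks[[1]]
  }
  if (length(blocks) == 0L) abort("need at least one feature block.")
  if (!all(vapply(blocks, inherits, logical(1), "feature_block"))) {
    abort("all arguments must be feature_block objects.")
  }
  gene_ids <- blocks[[1]]$gene_ids
  for (b in blocks) {
    if (!identical(b$gene_ids, gene_ids)) {
      abort("gene order differs between blocks; blocks must be built from the same gene table.")
    }
  }
  widths <- vapply(blocks, function(b) ncol(b$values), integer(1))
  values <- do.call(cbind, lapply(blocks, `[[`, "values"))
  if (anyDuplicated(colnames(values))) {
    abort("feature (column) names collide across blocks.")
  }
  boundaries <- tibble(
    block = vapply(blocks, `[[`, character(1), "name"),
    start = cumsum(c(1L, widths[-length(widths)])),
    end = cumsum(widths)
  )
  if (anyDuplicated(boundaries$block)) abort("block names must be unique.")
  structure(list(gene_ids = gene_ids, values = values,
                 boundaries = boundaries,
                 flagged = setNames(lapply(blocks, `[[`, "flagged"),
                                    boundaries$block)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d genes x %d features\n",
              nrow(x$values), ncol(x$values)))
  b <- x$boundaries
  for (i in seq_len(nrow(b))) {
    cat(sprintf("  %-12s columns %d-%d (width %d)\n",
                b$block[i], b$start[i], b$end[i], b$end[i] - b$start[i] + 1L))
  }
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Slice one block back out of a feature matrix
#'
#' @param fm A feature matrix from [assemble_features()].
#' @param block Block name.
#' @return The block's [feature_block()] (bit-identical to the input block).
#' @export
block_slice <- function(fm, block) {
  stopifnot(inherits(fm, "feature_matrix"))
  b <- fm$boundaries[fm$boundaries$block == block, ]
  if (nrow(b) == 0L) abort(sprintf("no block named \"%s\".", block))
  feature_block(block,
                fm$values[, b$start:b$end, drop = FALSE],
                fm$gene_ids,
                flagged = fm$flagged[[block]] %||% character())
}

#' Map each feature column to its block
#'
#' @param fm A feature matrix.
#' @return Tibble with columns `feature_id`, `block`, `column`.
#' @export
feature_map <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  b <- fm$boundaries
  tibble(
    feature_id = colnames(fm$values),
    block = rep(b$block, b$end - b$start + 1L),
    column = seq_len(ncol(fm$values))
  )
}
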