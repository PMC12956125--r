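#' Average (midrank) ranking
#'
#' Ascending ranks 1..n with tied values assigned the mean of the rank
#' positions they occupy: three tied smallest values each get
#' (1 + 2 + 3) / 3 = 2. Thin wrapper over [base::rank()] so the ranking
#' convention used by the screening statistic is explicit and testable.
#'
#' @param values Finite numeric vector.
#' @return Numeric vector of midranks.
#' @export
average_ranks <- function(values) {
  if (length(values) == 0L) abort("cannot rank an empty vector.")
  if (any(!is.finite(values))) abort("values must be finite.")
  rank(values, ties.method = "average")
}

#' Tie-corrected Mann-Whitney z-score
#'
#' Computes the rank-sum U statistic for two groups with midranks, the
#' expected value `mu_u = n1 n2 / 2`, and the tie-corrected standard
#' deviation
#' \deqn{\sigma = \sqrt{\frac{n_1 n_2}{n(n-1)}\Big(\frac{n^3-n}{12} -
#'   \sum_i \frac{t_i^3 - t_i}{12}\Big)}}
#' where \eqn{t_i} are the sizes of the tied groups. `U1` is oriented as the
#' number of pairwise wins of group 1 (plus half-ties), so a positive `z1`
#' means group 1 is stochastically larger; `z2 = -z1`. No continuity
#' correction is applied. When every value is tied, `sigma_corr` is 0 and
#' the z-scores are defined as 0 with `degenerate = TRUE`.
#'
#' @param group1,group2 Finite numeric vectors (each non-empty). Group 1 is
#'   the group whose enrichment the sign of `z1` reports (here, Mendelian
#'   genes).
#' @return One-row tibble with `n1`, `n2`, `T1`, `T2` (rank sums), `U1`,
#'   `U2`, `mu_u`, `sigma_corr`, `z1`, `z2`, `degenerate`, and a list column
#'   `tie_groups` of tie multiplicities.
#' @export
utest_z <- function(group1, group2) {
  n1 <- length(group1)
  n2 <- length(group2)
  if (n1 < 1L || n2 < 1L) abort("both groups must be non-empty.")
  if (any(!is.finite(c(group1, group2)))) abort("values must be finite.")
  r <- average_ranks(c(group1, group2))
  n <- n1 + n2
  T1 <- sum(r[seq_len(n1)])
  T2 <- sum(r[n1 + seq_len(n2)])
  U1 <- T1 - n1 * (n1 + 1) / 2 # pairwise wins of group 1 (ties count 1/2)
  U2 <- n1 * n2 - U1
  mu_u <- n1 * n2 / 2
  ties <- as.numeric(table(c(group1, group2)))
  ties <- ties[ties > 1L]
  u_corr <- sum(ties^3 - ties) / 12
  var_u <- n1 * n2 / (n * (n - 1)) * ((n^3 - n) / 12 - u_corr)
  sigma <- sqrt(max(var_u, 0))
  degenerate <- sigma == 0
  z1 <- if (degenerate) 0 else (U1 - mu_u) / sigma
  tibble(
    n1 = n1, n2 = n2, T1 = T1, T2 = T2, U1 = U1, U2 = U2,
    mu_u = mu_u, sigma_corr = sigma, z1 = z1, z2 = -z1,
    degenerate = degenerate, tie_groups = list(ties)
  )
}

# U1 and z1 for every column of a matrix against a 0/1 label vector.
# Same statistic as utest_z(), vectorised over columns.
column_z <- function(values, is_pos) {
  n1 <- sum(is_pos)
  n2 <- sum(!is_pos)
  n <- n1 + n2
  stats <- apply(values, 2L, function(v) {
    r <- rank(v, ties.method = "average")
    U1 <- sum(r[is_pos]) - n1 * (n1 + 1) / 2
    ties <- as.numeric(table(v))
    ties <- ties[ties > 1L]
    var_u <- n1 * n2 / (n * (n - 1)) *
      ((n^3 - n) / 12 - sum(ties^3 - ties) / 12)
    c(U1, if (var_u <= 0) 0 else (U1 - n1 * n2 / 2) / sqrt(var_u))
  })
  list(U1 = stats[1L, ], z1 = stats[2L, ])
}

#' Screen features by Mann-Whitney z-score
#'
#' For each feature column in the designated blocks, computes the
#' tie-corrected Mann-Whitney z-score contrasting Mendelian (label 1)
#' against unknown (label 0) genes, and keeps features with `z1` strictly
#' greater than `cutoff` (default 0.1). Columns of non-screened blocks
#' (aggregate scores, embeddings) pass through untouched. Screening is fit
#' on the full labeled set; the z-table doubles as the per-term importance
#' ranking.
#'
#' @param fm A feature matrix from [assemble_features()].
#' @param labels Gene label table (`gene_id`, `label`) covering the same
#'   genes.
#' @param cutoff Finite z-score cutoff; strict inequality, so features tied
#'   at exactly `cutoff` are dropped.
#' @param screen_blocks Names of blocks to screen (others pass through).
#' @return A `feature_screen`: list with `matrix` (reduced feature matrix),
#'   `z_table` (tibble `feature_id`, `block`, `n1`, `n2`, `U1`, `z1`,
#'   `screened`, `kept`), and `cutoff`. `tidy()` returns the z-table.
#' @export
screen_features <- function(fm, labels, cutoff = 0.1,
                            screen_blocks = c("pathway", "go_process")) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff)) {
    abort("`cutoff` must be a single finite number.")
  }
  labels <- align_labels(labels, fm$gene_ids)
  check_gene_table(labels, require_both_classes = TRUE)
  is_pos <- labels$label == 1L
  fmap <- feature_map(fm)
  screened <- fmap$block %in% screen_blocks
  z <- rep(NA_real_, nrow(fmap))
  u1 <- rep(NA_real_, nrow(fmap))
  if (any(screened)) {
    cs <- column_z(fm$values[, screened, drop = FALSE], is_pos)
    z[screened] <- cs$z1
    u1[screened] <- cs$U1
  }
  n1 <- sum(is_pos)
  n2 <- sum(!is_pos)
  z_table <- tibble(
    feature_id = fmap$feature_id, block = fmap$block,
    n1 = n1, n2 = n2, U1 = u1, z1 = z,
    screened = screened,
    kept = !screened | (!is.na(z) & z > cutoff)
  )
  keep_cols <- which(z_table$kept)
  blocks <- lapply(seq_len(nrow(fm$boundaries)), function(i) {
    b <- fm$boundaries[i, ]
    cols <- keep_cols[keep_cols >= b$start & keep_cols <= b$end]
    if (length(cols) == 0L) return(NULL)
    feature_block(b$block, fm$values[, cols, drop = FALSE], fm$gene_ids,
                  flagged = fm$flagged[[b$block]] %||% character())
  })
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  structure(list(matrix = assemble_features(blocks), z_table = z_table,
                 cutoff = cutoff),
            class = "feature_screen")
}

#' @export
print.feature_screen <- function(x, ...) {
  kept <- sum(x$z_table$kept & x$z_table$screened)
  tot <- sum(x$z_table$screened)
  cat(sprintf(
    "<feature_screen> z > %g kept %d of %d screened features (+%d pass-through)\n",
    x$cutoff, kept, tot, sum(!x$z_table$screened)))
  invisible(x)
}

#' @describeIn screen_features The per-feature z-table.
#' @param x A `feature_screen`.
#' @param ... Unused.
#' @method tidy feature_screen
#' @export
tidy.feature_screen <- function(x, ...) x$z_table
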