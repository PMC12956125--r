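#' Protein-protein interaction degrees from confidence-filtered edge lists
#'
#' Filters each edge list at its own confidence cutoff (edges with
#' `score >= cutoff` are kept; defaults 500 for STRING-like integer scores
#' and 0.5 for HIPPIE-like real confidences), removes self-loops, takes the
#' union of the filtered networks as an undirected simple graph, and counts
#' each gene's unique interaction partners. A pair present in both sources
#' counts once.
#'
#' @param edges Named list of edge tibbles (`gene_a`, `gene_b`, `score`),
#'   e.g. `list(string = ..., hippie = ...)`.
#' @param cutoffs Numeric vector of per-source cutoffs, matched to `edges`
#'   by name (default `c(string = 500, hippie = 0.5)`).
#' @param by_source Also return per-source degree columns (diagnostic).
#' @return Tibble with `gene_id` and `degree` for every gene with at least
#'   one passing edge (plus `degree_<source>` columns if `by_source`).
#' @export
combined_degrees <- function(edges, cutoffs = c(string = 500, hippie = 0.5),
                             by_source = FALSE) {
  if (!is.list(edges) || is.null(names(edges))) {
    abort("`edges` must be a named list of edge tables.")
  }
  filtered <- lapply(names(edges), function(src) {
    e <- edges[[src]]
    if (!all(c("gene_a", "gene_b", "score") %in% names(e))) {
      abort("edge tables need columns `gene_a`, `gene_b`, `score`.")
    }
    if (any(e$score < 0)) abort("edge scores must be non-negative.")
    cut <- cutoffs[[src]]
    if (is.null(cut) || is.na(cut)) {
      abort(sprintf("no cutoff supplied for source \"%s\".", src))
    }
    e <- e[e$score >= cut & e$gene_a != e$gene_b, c("gene_a", "gene_b")]
    dplyr::mutate(e, source = src)
  })
  all_edges <- dplyr::bind_rows(filtered)
  if (nrow(all_edges) == 0L) {
    out <- tibble(gene_id = character(), degree = integer())
    return(out)
  }
  # canonical undirected pair
  pairs <- tibble(
    a = pmin(all_edges$gene_a, all_edges$gene_b),
    b = pmax(all_edges$gene_a, all_edges$gene_b),
    source = all_edges$source
  )
  degree_of <- function(p) {
    p <- dplyr::distinct(p, .data$a, .data$b)
    tab <- table(c(p$a, p$b))
    tibble(gene_id = names(tab), degree = as.integer(tab))
  }
  out <- degree_of(pairs)
  if (by_source) {
    for (src in names(edges)) {
      d <- degree_of(pairs[pairs$source == src, ])
      names(d)[2] <- paste0("degree_", src)
      out <- dplyr::left_join(out, d, by = "gene_id")
      out[[paste0("degree_", src)]][is.na(out[[paste0("degree_", src)]])] <- 0L
    }
  }
  dplyr::arrange(out, .data$gene_id)
}

#' Per-term network and age statistics
#'
#' For every term of a catalog: its screening z-score, the maximal PPI
#' degree over member genes with degree data, and the minimal LCA
#' (evolutionary age class, 1 = oldest) over members with age data. Terms
#' whose members all lack the respective data get `NA` and should be
#' excluded from the corresponding correlation population.
#'
#' @param catalog A [term_catalog()].
#' @param z_table Tibble with `feature_id` and `z1` columns (the
#'   [screen_features()] z-table).
#' @param degrees Tibble from [combined_degrees()].
#' @param lca Tibble with `gene_id`, `lca`.
#' @return Tibble with `term_id`, `namespace`, `n_members`, `z`, `max_ppi`,
#'   `min_lca`.
#' @export
term_stats <- function(catalog, z_table, degrees = NULL, lca = NULL) {
  stopifnot(inherits(catalog, "term_catalog"))
  z <- z_table$z1[match(names(catalog$terms), z_table$feature_id)]
  max_ppi <- rep(NA_integer_, length(catalog$terms))
  min_lca <- rep(NA_integer_, length(catalog$terms))
  for (i in seq_along(catalog$terms)) {
    members <- catalog$terms[[i]]
    if (!is.null(degrees)) {
      d <- degrees$degree[degrees$gene_id %in% members]
      if (length(d) > 0L) max_ppi[i] <- max(d)
    }
    if (!is.null(lca)) {
      a <- lca$lca[lca$gene_id %in% members]
      if (length(a) > 0L) min_lca[i] <- min(a)
    }
  }
  tibble(
    term_id = names(catalog$terms),
    namespace = catalog$namespace,
    n_members = lengths(catalog$terms),
    z = z, max_ppi = max_ppi, min_lca = min_lca
  )
}

#' Pearson correlation with a t-transform p-value
#'
#' Sample Pearson correlation between two equally long vectors and the
#' two-sided p-value from the t transform (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors, length >= 3, each with nonzero variance.
#' @return One-row tibble with `r`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3L) abort("need at least 3 complete pairs.")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    abort("correlation is undefined for zero-variance input.")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Per-gene maximal term z-score
#'
#' A gene's maximal z is the largest screening z-score over all terms of
#' the catalog it belongs to; genes in no term get `NA`.
#'
#' @param catalog A [term_catalog()].
#' @param z_table Tibble with `feature_id`, `z1`.
#' @param gene_ids Genes to report (default: all genes in the catalog).
#' @return Tibble with `gene_id`, `max_z`.
#' @export
gene_max_z <- function(catalog, z_table, gene_ids = NULL) {
  stopifnot(inherits(catalog, "term_catalog"))
  long <- as_tibble(catalog)
  long$z <- z_table$z1[match(long$term_id, z_table$feature_id)]
  by_gene <- long |>
    dplyr::filter(!is.na(.data$z)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(max_z = max(.data$z), .groups = "drop")
  if (is.null(gene_ids)) return(by_gene)
  tibble(gene_id = as.character(gene_ids)) |>
    dplyr::left_join(by_gene, by = "gene_id")
}
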