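# Readers and writers for the package's TSV/JSON artifact dialects.
# All tables are tab-separated with a header row.

#' Read a two-column gene label table
#'
#' @param path TSV with columns `gene_id`, `label` (1 = Mendelian/positive,
#'   0 = unknown).
#' @return Tibble with `gene_id` (character) and `label` (integer).
#' @export
read_gene_labels <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), label = readr::col_integer()))
  check_gene_table(tbl)
  tbl
}

#' Read a per-variant score table
#'
#' @param path TSV with columns `gene_id`, `kind`, `score`.
#' @return Tibble validated for the score-table contract.
#' @export
read_variant_scores <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), kind = readr::col_character(),
    score = readr::col_double()))
  check_score_table(tbl)
  tbl
}

#' Read a per-gene embedding table
#'
#' @param path TSV whose first column is `gene_id` followed by a fixed
#'   number of numeric columns. Ragged or non-numeric rows are an error.
#' @return Tibble (gene_id + numeric columns).
#' @export
read_embeddings <- function(path) {
  tbl <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double())))
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0L) {
    abort(sprintf("malformed embedding file %s (first problem: row %d, %s).",
                  path, prob$row[[1]], prob$expected[[1]]))
  }
  if (ncol(tbl) < 2L) abort("embedding file has no numeric columns.")
  tbl
}

#' Read a protein-protein interaction edge list
#'
#' Two dialects: STRING-like (`protein1`, `protein2`, `combined_score` as an
#' integer in 0-1000) and HIPPIE-like (`idA`, `idB`, `confidence` as a real
#' in 0-1). Either is normalised to columns `gene_a`, `gene_b`, `score`.
#'
#' @param path Edge list TSV.
#' @return Tibble with `gene_a`, `gene_b`, `score`.
#' @export
read_edges <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols())
  nm <- names(tbl)
  if (all(c("protein1", "protein2", "combined_score") %in% nm)) {
    tbl <- tibble(gene_a = as.character(tbl$protein1),
                  gene_b = as.character(tbl$protein2),
                  score = as.numeric(tbl$combined_score))
  } else if (all(c("idA", "idB", "confidence") %in% nm)) {
    tbl <- tibble(gene_a = as.character(tbl$idA),
                  gene_b = as.character(tbl$idB),
                  score = as.numeric(tbl$confidence))
  } else if (all(c("gene_a", "gene_b", "score") %in% nm)) {
    tbl <- tbl[, c("gene_a", "gene_b", "score")]
  } else {
    abort(paste0("unrecognised edge-list columns in ", path))
  }
  if (any(!is.finite(tbl$score)) || any(tbl$score < 0)) {
    abort("edge scores must be finite and non-negative.")
  }
  tbl
}

#' Read a per-gene evolutionary age (LCA) table
#'
#' @param path TSV with columns `gene_id`, `lca` (integer 1-31; 1 = oldest,
#'   origin of life).
#' @return Tibble with `gene_id`, `lca`.
#' @export
read_lca <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), lca = readr::col_integer()))
  if (any(tbl$lca < 1L | tbl$lca > 31L)) {
    abort("LCA values must be integers in [1, 31].")
  }
  tbl
}

#' Write / read a feature matrix as TSV plus a JSON block sidecar
#'
#' The TSV holds `gene_id` plus one column per feature; the sidecar JSON
#' records block names and column boundaries so the block structure survives
#' a round trip.
#'
#' @param fm A feature matrix from [assemble_features()].
#' @param path Output TSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  tbl <- dplyr::bind_cols(tibble(gene_id = fm$gene_ids),
                          as_tibble(fm$values, .name_repair = "minimal"))
  readr::write_tsv(tbl, path)
  jsonlite::write_json(
    list(blocks = fm$boundaries, flagged = fm$flagged),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  values <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(values) <- tbl$gene_id
  blocks <- lapply(seq_len(nrow(side$blocks)), function(i) {
    nm <- side$blocks$block[[i]]
    feature_block(nm,
                  values[, side$blocks$start[[i]]:side$blocks$end[[i]],
                         drop = FALSE],
                  tbl$gene_id,
                  flagged = unlist(side$flagged[[nm]]) %||% character())
  })
  assemble_features(blocks)
}
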