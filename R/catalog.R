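#' Gene-set catalogs
#'
#' A term catalog maps term identifiers (Reactome-like pathways or GO
#' biological processes) to sets of member genes. Term order is the order of
#' first appearance in the source file and is frozen into downstream feature
#' column order, so catalog files fully determine the feature layout.
#'
#' @param terms Named list of character vectors: `term_id -> member gene ids`.
#' @param namespace `"pathway"` or `"go_process"`.
#' @return A `term_catalog` object.
#' @export
term_catalog <- function(terms, namespace = c("pathway", "go_process")) {
  namespace <- match.arg(namespace)
  if (!is.list(terms) || is.null(names(terms)) || any(names(terms) == "")) {
    abort("`terms` must be a named list of character vectors.")
  }
  if (anyDuplicated(names(terms))) {
    abort("term ids must be unique within a namespace.")
  }
  terms <- lapply(terms, function(m) unique(as.character(m)))
  if (any(lengths(terms) == 0L)) {
    abort("every term must have at least one member gene.")
  }
  structure(list(namespace = namespace, terms = terms),
            class = "term_catalog")
}

#' Read a gene-set catalog file
#'
#' Accepts the GMT dialect (`term_id <TAB> description <TAB> member...`, one
#' term per line) or a two-column TSV of `gene_id <TAB> term_id` pairs (with
#' or without a header line named `gene_id`). Membership is deduplicated;
#' term order is first appearance.
#'
#' @param path Path to the catalog file.
#' @param namespace `"pathway"` or `"go_process"`.
#' @param format `"auto"` (default; sniff from the first line), `"gmt"` or
#'   `"tsv"`.
#' @return A [term_catalog()].
#' @export
read_catalog <- function(path, namespace = c("pathway", "go_process"),
                         format = c("auto", "gmt", "tsv")) {
  namespace <- match.arg(namespace)
  format <- match.arg(format)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    abort(paste0("catalog file is empty: ", path))
  }
  if (format == "auto") {
    nfield <- length(strsplit(lines[[1]], "\t", fixed = TRUE)[[1]])
    format <- if (nfield >= 3L) "gmt" else "tsv"
  }
  if (format == "gmt") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 3L)
    if (length(bad) > 0L) {
      abort(sprintf("malformed GMT line %d in %s: expected at least 3 fields.",
                    bad[[1]], path))
    }
    ids <- vapply(fields, `[[`, character(1), 1L)
    members <- lapply(fields, function(f) f[-(1:2)])
    keep <- !duplicated(ids)
    terms <- setNames(members[keep], ids[keep])
    if (any(!keep)) {
      for (id in unique(ids[!keep])) {
        terms[[id]] <- c(terms[[id]], unlist(members[ids == id & !keep]))
      }
    }
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != 2L)
    if (length(bad) > 0L) {
      abort(sprintf("malformed line %d in %s: expected 2 tab-separated fields.",
                    bad[[1]], path))
    }
    gene <- vapply(fields, `[[`, character(1), 1L)
    term <- vapply(fields, `[[`, character(1), 2L)
    if (gene[[1]] == "gene_id") { # header row
      gene <- gene[-1]
      term <- term[-1]
    }
    if (length(gene) == 0L) abort(paste0("catalog file has no rows: ", path))
    terms <- split(gene, factor(term, levels = unique(term)))
  }
  term_catalog(terms, namespace)
}

#' @export
print.term_catalog <- function(x, ...) {
  cat(sprintf("<term_catalog> namespace=%s, %d terms, %d distinct genes\n",
              x$namespace, length(x$terms),
              length(unique(unlist(x$terms, use.names = FALSE)))))
  invisible(x)
}

#' @export
length.term_catalog <- function(x) length(x$terms)

#' Long-format view of a catalog
#'
#' @param x A [term_catalog()].
#' @param ... Unused.
#' @return Tibble with columns `term_id`, `gene_id`, `namespace`.
#' @method as_tibble term_catalog
#' @importFrom tibble as_tibble
#' @export
as_tibble.term_catalog <- function(x, ...) {
  tibble(
    term_id = rep(names(x$terms), lengths(x$terms)),
    gene_id = unlist(x$terms, use.names = FALSE),
    namespace = x$namespace
  )
}
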