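# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb the
# user's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a deterministic 31-bit sub-seed from a base seed and a stream label,
# so each synthetic-data component draws from its own substream.
derive_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

check_gene_table <- function(genes, require_both_classes = FALSE) {
  if (!is.data.frame(genes) || !all(c("gene_id", "label") %in% names(genes))) {
    abort("`genes` must be a data frame with columns `gene_id` and `label`.")
  }
  if (anyDuplicated(genes$gene_id)) {
    abort("`gene_id` values must be unique.")
  }
  if (!all(genes$label %in% c(0L, 1L))) {
    abort("`label` must be 0 (unknown) or 1 (Mendelian/positive).")
  }
  if (require_both_classes && length(unique(genes$label)) < 2L) {
    abort("both labels (0 and 1) must be present.")
  }
  invisible(genes)
}

# Align a label table to an ordered gene-id vector; errors on any mismatch.
align_labels <- function(genes, gene_ids) {
  check_gene_table(genes)
  if (!setequal(genes$gene_id, gene_ids) ||
      length(genes$gene_id) != length(gene_ids)) {
    abort("label table and feature matrix cover different gene sets.")
  }
  genes[match(gene_ids, genes$gene_id), , drop = FALSE]
}
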