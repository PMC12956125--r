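#' Simulate a full planted-signal input bundle
#'
#' Deterministically generates every input the pipeline consumes — gene
#' labels, two gene-set catalogs, per-gene embeddings, a per-variant score
#' table, two confidence-scored PPI edge lists, and a per-gene LCA age
#' table — with tunable planted signal:
#'
#' * a fixed fraction of terms in each catalog is *enriched*: positive
#'   genes' membership odds are multiplied by `enrich_odds`;
#' * positive genes' latent aggregate variant scores are shifted so that
#'   each score column alone separates the classes at roughly
#'   `score_auc` (two-component Gaussian mixture);
#' * positive genes' embeddings are mean-shifted by `embed_shift` per
#'   dimension;
#' * positive genes get on average `degree_boost` extra interaction
#'   partners and LCA ages shifted `lca_shift` classes older (towards 1).
#'
#' Each component draws from its own seed substream, so changing one
#' component's parameters does not perturb the draws of the others, and the
#' whole bundle is bit-identical for identical `(config, seed)`.
#'
#' @param n_genes Number of genes.
#' @param prevalence Positive fraction; the positive count is
#'   `floor(n_genes * prevalence + 0.5)`.
#' @param n_pathways,n_go_terms Catalog sizes.
#' @param frac_enriched Fraction of terms per catalog that carry planted
#'   signal.
#' @param enrich_odds Membership odds multiplier for positives in enriched
#'   terms (> 0; 1 = no signal).
#' @param base_membership Baseline per-(gene, term) membership probability.
#' @param embed_dim Embedding width.
#' @param embed_shift Per-dimension mean shift of positive embeddings.
#' @param score_auc Target standalone AUC of each aggregate-score column
#'   (0.5 = chance).
#' @param base_degree Expected PPI degree before filtering.
#' @param degree_boost Expected extra partners for positive genes.
#' @param lca_shift Downward (older) shift of positive genes' LCA class.
#' @param seed Integer master seed.
#' @return A `sim_bundle` list: `labels`, `pathways`, `go` (catalogs),
#'   `embeddings`, `scores`, `edges` (list `string`, `hippie`), `lca`,
#'   `enriched` (list of planted term ids per namespace), `config`.
#' @export
simulate_mendelian_data <- function(n_genes = 2000L, prevalence = 0.27,
                                    n_pathways = 200L, n_go_terms = 500L,
                                    frac_enriched = 0.1, enrich_odds = 6,
                                    base_membership = 0.05,
                                    embed_dim = 64L, embed_shift = 0.1,
                                    score_auc = 0.78,
                                    base_degree = 8, degree_boost = 15,
                                    lca_shift = 8L, seed = 1L) {
  if (prevalence <= 0 || prevalence >= 1) {
    abort("`prevalence` must be in (0, 1).")
  }
  if (enrich_odds <= 0) abort("`enrich_odds` must be > 0.")
  if (any(c(n_genes, n_pathways, n_go_terms, embed_dim) < 1L)) {
    abort("all counts must be >= 1.")
  }
  config <- list(
    n_genes = as.integer(n_genes), prevalence = prevalence,
    n_pathways = as.integer(n_pathways), n_go_terms = as.integer(n_go_terms),
    frac_enriched = frac_enriched, enrich_odds = enrich_odds,
    base_membership = base_membership, embed_dim = as.integer(embed_dim),
    embed_shift = embed_shift, score_auc = score_auc,
    base_degree = base_degree, degree_boost = degree_boost,
    lca_shift = as.integer(lca_shift), seed = as.integer(seed)
  )
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  n_pos <- as.integer(floor(n_genes * prevalence + 0.5))

  labels <- with_seed(derive_seed(seed, "labels"), {
    pos <- sample.int(n_genes, n_pos)
    tibble(gene_id = gene_ids,
           label = as.integer(seq_len(n_genes) %in% pos))
  })
  is_pos <- labels$label == 1L

  sim_catalog <- function(prefix, n_terms, namespace, stream) {
    with_seed(derive_seed(seed, stream), {
      term_ids <- sprintf("%s%04d", prefix, seq_len(n_terms))
      n_enr <- ceiling(frac_enriched * n_terms)
      enriched <- sort(sample.int(n_terms, n_enr))
      p_base <- base_membership
      odds <- p_base / (1 - p_base) * enrich_odds
      p_enr <- odds / (1 + odds)
      terms <- vector("list", n_terms)
      for (t in seq_len(n_terms)) {
        p <- rep(p_base, n_genes)
        if (t %in% enriched) p[is_pos] <- p_enr
        members <- gene_ids[runif(n_genes) < p]
        if (length(members) == 0L) members <- gene_ids[sample.int(n_genes, 1L)]
        terms[[t]] <- members
      }
      list(catalog = term_catalog(setNames(terms, term_ids), namespace),
           enriched = term_ids[enriched])
    })
  }
  pw <- sim_catalog("PTH", n_pathways, "pathway", "pathways")
  go <- sim_catalog("GOBP", n_go_terms, "go_process", "go")

  embeddings <- with_seed(derive_seed(seed, "embeddings"), {
    m <- matrix(rnorm(n_genes * embed_dim), n_genes, embed_dim)
    m[is_pos, ] <- m[is_pos, ] + embed_shift
    out <- as_tibble(m, .name_repair = ~ sprintf("emb_%03d", seq_len(embed_dim)))
    dplyr::bind_cols(tibble(gene_id = gene_ids), out)
  })

  scores <- with_seed(derive_seed(seed, "scores"), {
    delta <- sqrt(2) * qnorm(score_auc) # per-column class separation
    rows <- list()
    for (kind in c("missense", "nonsense")) {
      latent <- rnorm(n_genes, mean = ifelse(is_pos, delta, 0))
      n_var <- rpois(n_genes, 3) + 1L
      rows[[kind]] <- tibble(
        gene_id = rep(gene_ids, n_var),
        kind = kind,
        score = rep(latent, n_var) + rnorm(sum(n_var), sd = 0.5)
      )
    }
    dplyr::bind_rows(rows)
  })

  edges <- with_seed(derive_seed(seed, "network"), {
    m_base <- as.integer(round(n_genes * base_degree / 2))
    a <- sample(gene_ids, m_base, replace = TRUE)
    b <- sample(gene_ids, m_base, replace = TRUE)
    extra <- rpois(n_pos, degree_boost)
    a <- c(a, rep(gene_ids[is_pos], extra))
    b <- c(b, sample(gene_ids, sum(extra), replace = TRUE))
    keep <- a != b
    a <- a[keep]
    b <- b[keep]
    src <- runif(length(a)) < 0.5
    list(
      string = tibble(gene_a = a[src], gene_b = b[src],
                      score = as.numeric(sample.int(1000, sum(src),
                                                    replace = TRUE))),
      hippie = tibble(gene_a = a[!src], gene_b = b[!src],
                      score = round(runif(sum(!src)), 3))
    )
  })

  lca <- with_seed(derive_seed(seed, "lca"), {
    # Young age classes are made common and ancient ones rare so that the
    # per-term *minimum* LCA still varies across terms of ~100 members;
    # a uniform age distribution would drive every term minimum to 1.
    age <- sample.int(31L, n_genes, replace = TRUE, prob = (1:31)^2)
    age[is_pos] <- pmax(1L, age[is_pos] - as.integer(lca_shift))
    tibble(gene_id = gene_ids, lca = age)
  })

  structure(list(labels = labels, pathways = pw$catalog, go = go$catalog,
                 embeddings = embeddings, scores = scores, edges = edges,
                 lca = lca,
                 enriched = list(pathway = pw$enriched, go_process = go$enriched),
                 config = config),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf(
    "<sim_bundle> %d genes (%d positive), %d pathways, %d GO terms, %d-dim embeddings\n",
    x$config$n_genes, sum(x$labels$label), length(x$pathways),
    length(x$go), x$config$embed_dim))
  invisible(x)
}

#' Assemble the feature matrix of a simulated (or real) input bundle
#'
#' Block order: aggregate scores (2 columns), pathway membership, GO-process
#' membership, embeddings.
#'
#' @param bundle A `sim_bundle`, or any list with `labels`, `pathways`,
#'   `go`, `embeddings`, `scores`.
#' @return A feature matrix from [assemble_features()].
#' @export
bundle_features <- function(bundle) {
  assemble_features(
    score_block(bundle$scores, bundle$labels),
    membership_block(bundle$pathways, bundle$labels),
    membership_block(bundle$go, bundle$labels),
    embedding_block(bundle$embeddings, bundle$labels)
  )
}

#' Write a bundle to disk in the package's file dialects
#'
#' Writes `labels.tsv`, `pathways.gmt`, `go.gmt`, `embeddings.tsv`,
#' `variant_scores.tsv`, `string_edges.tsv`, `hippie_edges.tsv`, `lca.tsv`
#' and a `manifest.json` recording the generating config and the md5 of
#' every file.
#'
#' @param bundle A `sim_bundle`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  readr::write_tsv(bundle$labels, p("labels.tsv"))
  write_gmt <- function(catalog, path) {
    lines <- vapply(seq_along(catalog$terms), function(i) {
      paste(c(names(catalog$terms)[i], "synthetic", catalog$terms[[i]]),
            collapse = "\t")
    }, character(1))
    readr::write_lines(lines, path)
  }
  write_gmt(bundle$pathways, p("pathways.gmt"))
  write_gmt(bundle$go, p("go.gmt"))
  readr::write_tsv(bundle$embeddings, p("embeddings.tsv"))
  readr::write_tsv(bundle$scores, p("variant_scores.tsv"))
  readr::write_tsv(
    setNames(bundle$edges$string, c("protein1", "protein2", "combined_score")),
    p("string_edges.tsv"))
  readr::write_tsv(
    setNames(bundle$edges$hippie, c("idA", "idB", "confidence")),
    p("hippie_edges.tsv"))
  readr::write_tsv(bundle$lca, p("lca.tsv"))
  files <- c("labels.tsv", "pathways.gmt", "go.gmt", "embeddings.tsv",
             "variant_scores.tsv", "string_edges.tsv", "hippie_edges.tsv",
             "lca.tsv")
  jsonlite::write_json(
    list(config = bundle$config,
         enriched = bundle$enriched,
         md5 = as.list(tools::md5sum(file.path(dir, files)))),
    p("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' The hand-checked worked example
#'
#' A fixed 12-gene, 5-pathway dataset shipped with the package, small
#' enough that every intermediate quantity (midranks, U, z, the calibration
#' curve, enrichment factors, iterated targets) was computed by brute-force
#' enumeration and frozen as golden files. Useful for demonstrating the
#' method and as an exact regression anchor.
#'
#' @return List with the input tables (`labels`, `pathways`, `go`,
#'   `embeddings`, `scores`, `edges`, `lca`), a fixed `round1` score table,
#'   and `golden` (tibbles `utest`, `calibration`, `targets`, `metrics`).
#' @export
worked_example <- function() {
  dir <- system.file("extdata", "worked_example", package = "mendelprio")
  if (dir == "") abort("worked example data not installed.")
  p <- function(f) file.path(dir, f)
  list(
    labels = read_gene_labels(p("labels.tsv")),
    pathways = read_catalog(p("pathways.gmt"), "pathway"),
    go = read_catalog(p("go.gmt"), "go_process"),
    embeddings = read_embeddings(p("embeddings.tsv")),
    scores = read_variant_scores(p("variant_scores.tsv")),
    edges = list(string = read_edges(p("string_edges.tsv")),
                 hippie = read_edges(p("hippie_edges.tsv"))),
    lca = read_lca(p("lca.tsv")),
    round1 = readr::read_tsv(p("round1_scores.tsv"),
                             col_types = readr::cols(
                               gene_id = readr::col_character(),
                               score = readr::col_double())),
    golden = list(
      utest = readr::read_tsv(p("golden/utest.tsv"),
                              col_types = readr::cols()),
      calibration = readr::read_tsv(p("golden/calibration.tsv"),
                                    col_types = readr::cols()),
      targets = readr::read_tsv(p("golden/targets.tsv"),
                                col_types = readr::cols()),
      metrics = readr::read_tsv(p("golden/metrics.tsv"),
                                col_types = readr::cols())
    )
  )
}
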