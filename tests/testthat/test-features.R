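test_that("GMT and two-column catalogs parse with set semantics", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("P1\tdesc\tG1\tG2", "P2\tdesc\tG2\tG2\tG3"), gmt)
  cat <- read_catalog(gmt, "pathway")
  expect_equal(length(cat), 2L)
  expect_setequal(cat$terms$P1, c("G1", "G2"))
  expect_equal(cat$terms$P2, c("G2", "G3")) # duplicate member deduplicated

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tterm_id", "G1\tP1", "G2\tP1", "G3\tP2"), tsv)
  cat2 <- read_catalog(tsv, "go_process")
  expect_setequal(cat2$terms$P1, c("G1", "G2"))
  expect_equal(cat2$namespace, "go_process")

  bad <- withr::local_tempfile()
  writeLines(c("P1\tdesc\tG1", "orphan-line"), bad)
  expect_error(read_catalog(bad, "pathway", format = "gmt"), "line 2")
  empty <- withr::local_tempfile()
  writeLines(character(), empty)
  expect_error(read_catalog(empty, "pathway"), "empty")
})

test_that("GMT parsing agrees with an independent reader", {
  skip_if_not_installed("fgsea")
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("A\tna\tG1\tG5\tG2", "B\tna\tG9", "C\tna\tG2\tG3\tG4\tG1"),
             gmt)
  ours <- read_catalog(gmt, "pathway")
  ref <- fgsea::gmtPathways(gmt)
  expect_identical(names(ours$terms), names(ref))
  for (t in names(ref)) expect_setequal(ours$terms[[t]], ref[[t]])
})

test_that("catalogs at the reference sizes give the stated block widths", {
  genes <- tibble::tibble(gene_id = c("G1", "G2", "G3"), label = c(1L, 0L, 0L))
  make_cat <- function(n, prefix, ns) {
    gmt <- withr::local_tempfile(fileext = ".gmt", .local_envir = parent.frame())
    writeLines(sprintf("%s%05d\td\tG%d", prefix, seq_len(n),
                       (seq_len(n) %% 3) + 1), gmt)
    read_catalog(gmt, ns)
  }
  pw <- make_cat(2363, "R-HSA-", "pathway")
  go <- make_cat(12535, "GO:", "go_process")
  expect_equal(length(pw), 2363L)
  expect_equal(length(go), 12535L)
  pw_block <- membership_block(pw, genes)
  go_block <- membership_block(go, genes)
  expect_equal(ncol(pw_block$values), 2364L)
  expect_equal(ncol(go_block$values), 12536L)

  emb <- tibble::as_tibble(
    matrix(rnorm(3 * 1024), 3, dimnames = list(NULL, sprintf("e%d", 1:1024))))
  emb <- dplyr::bind_cols(tibble::tibble(gene_id = genes$gene_id), emb)
  emb_block <- embedding_block(emb, genes)
  expect_equal(ncol(emb_block$values), 1024L)

  scores <- tibble::tibble(gene_id = rep(genes$gene_id, each = 2),
                           kind = rep(c("missense", "nonsense"), 3),
                           score = runif(6))
  fm <- assemble_features(score_block(scores, genes), pw_block, go_block,
                          emb_block)
  expect_equal(ncol(fm$values), 15926L)
})

test_that("membership blocks are binary with an exact trailing count", {
  genes <- tibble::tibble(gene_id = sprintf("G%d", 1:6),
                          label = c(1L, 1L, 0L, 0L, 0L, 0L))
  cat <- term_catalog(list(A = c("G1", "G2"), B = c("G1", "G3", "G5"),
                           C = "G1", D = c("G2", "G4"), E = "G6"),
                      "pathway")
  blk <- membership_block(cat, genes)
  expect_equal(ncol(blk$values), 6L) # 5 terms + count
  binary <- blk$values[, 1:5]
  expect_true(all(binary %in% c(0, 1)))
  expect_equal(unname(blk$values[, 6]), unname(rowSums(binary)))
  expect_equal(unname(blk$values["G1", ]), c(1, 1, 1, 0, 0, 3))
  # gene in no term: all zero, count 0
  genes2 <- dplyr::bind_rows(genes, tibble::tibble(gene_id = "G9", label = 0L))
  blk2 <- membership_block(cat, genes2)
  expect_equal(unname(blk2$values["G9", ]), rep(0, 6))
})

test_that("aggregate gene scores are means, permutation-invariant, zero-filled when absent", {
  tbl <- tibble::tibble(
    gene_id = c("G1", "G1", "G1", "G2", "G2"),
    kind = c("missense", "missense", "missense", "missense", "nonsense"),
    score = c(0.2, 0.4, 0.6, 0.7, 0.3))
  expect_equal(aggregate_gene_score(tbl, "G1", "missense"), 0.4)
  expect_equal(aggregate_gene_score(tbl, "G2", "missense"), 0.7)
  expect_true(is.na(aggregate_gene_score(tbl, "G1", "nonsense")))

  withr::with_seed(3, {
    for (i in 1:20) {
      s <- runif(sample.int(30, 1))
      t1 <- tibble::tibble(gene_id = "G", kind = "missense", score = s)
      t2 <- t1[sample.int(nrow(t1)), ]
      expect_equal(aggregate_gene_score(t1, "G", "missense"),
                   aggregate_gene_score(t2, "G", "missense"),
                   tolerance = 1e-12)
      expect_equal(aggregate_gene_score(t1, "G", "missense"), sum(s) / length(s),
                   tolerance = 1e-12)
    }
  })

  genes <- tibble::tibble(gene_id = c("G1", "G2", "G3"), label = c(1L, 0L, 0L))
  blk <- score_block(tbl, genes)
  expect_equal(unname(blk$values["G1", ]), c(0.4, 0)) # no nonsense rows -> 0
  expect_equal(unname(blk$values["G3", ]), c(0, 0))
  expect_true(all(c("G1", "G3") %in% blk$flagged))
  expect_false("G2" %in% blk$flagged)
})

test_that("embedding blocks validate input and zero-fill missing genes", {
  genes <- tibble::tibble(gene_id = c("G1", "G2", "G3"), label = c(1L, 0L, 0L))
  emb <- tibble::tibble(gene_id = c("G1", "G3"), e1 = c(1, 2), e2 = c(3, 4))
  blk <- embedding_block(emb, genes)
  expect_equal(unname(blk$values["G2", ]), c(0, 0))
  expect_equal(blk$flagged, "G2")
  expect_equal(unname(blk$values["G3", ]), c(2, 4))

  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\te1\te2", "G1\t0.5\toops", "G2\t1\t2"), path)
  expect_error(read_embeddings(path), "malformed")
})

test_that("assembly records boundaries, round-trips blocks bit-exactly, and rejects misaligned genes", {
  b <- tiny_bundle()
  fm <- bundle_features(b)
  widths <- fm$boundaries$end - fm$boundaries$start + 1L
  expect_equal(sum(widths), ncol(fm$values))
  expect_equal(fm$boundaries$block,
               c("scores", "pathway", "go_process", "embedding"))
  for (blk in fm$boundaries$block) {
    sliced <- block_slice(fm, blk)
    expect_identical(sliced$values,
                     fm$values[, fm$boundaries$start[fm$boundaries$block == blk]:
                                  fm$boundaries$end[fm$boundaries$block == blk],
                               drop = FALSE])
  }
  # single block assembly is the identity on values
  single <- assemble_features(block_slice(fm, "scores"))
  expect_identical(single$values, block_slice(fm, "scores")$values)

  shuffled <- b$labels[rev(seq_len(nrow(b$labels))), ]
  expect_error(
    assemble_features(score_block(b$scores, b$labels),
                      membership_block(b$pathways, shuffled)),
    "gene order")
})

test_that("feature matrices survive a TSV + sidecar round trip", {
  b <- tiny_bundle(seed = 4L, n_genes = 40L)
  fm <- bundle_features(b)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(back$gene_ids, fm$gene_ids)
  expect_equal(back$boundaries, fm$boundaries)
  expect_equal(back$values, fm$values, tolerance = 1e-12)
  expect_setequal(back$flagged$scores, fm$flagged$scores)
})
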