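# Brute-force oracles, kept independent of the package implementation.

# U statistic of group 1 by exhaustive pairwise comparison (ties count 1/2).
oracle_u <- function(g1, g2) {
  u <- 0
  for (a in g1) for (b in g2) u <- u + (a > b) + 0.5 * (a == b)
  u
}

# Midranks by explicit averaging of occupied rank positions.
oracle_ranks <- function(v) {
  n <- length(v)
  ord <- order(v)
  rk <- numeric(n)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && v[ord[j + 1]] == v[ord[i]]) j <- j + 1
    rk[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  rk
}

# AUC as the O(n^2) mean pairwise win rate of positives over negatives.
oracle_auc <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Inclusive precision calibration by direct threshold sweep.
oracle_calibration <- function(score, label) {
  th <- sort(unique(score))
  data.frame(
    threshold = th,
    n_above = vapply(th, function(t) sum(score >= t), numeric(1)),
    n_pos_above = vapply(th, function(t) sum(score >= t & label == 1),
                         numeric(1)),
    precision = vapply(th, function(t) {
      sum(score >= t & label == 1) / sum(score >= t)
    }, numeric(1))
  )
}

# Top-k enrichment by direct counting (ties broken by ascending gene_id).
oracle_ef <- function(gene_id, score, label, k) {
  ord <- order(-score, gene_id)
  (sum(label[ord][seq_len(k)] == 1) / k) / (mean(label == 1))
}

# Small tie-rich random two-group samples for property loops.
random_groups <- function(n_max = 12, alphabet = 0:3) {
  n1 <- sample.int(n_max - 1L, 1L)
  n2 <- sample.int(n_max - n1, 1L)
  list(g1 = sample(alphabet, n1, replace = TRUE),
       g2 = sample(alphabet, n2, replace = TRUE))
}

# Cheap shared fixture: tiny simulated bundle with planted signal.
tiny_bundle <- function(seed = 11L, n_genes = 150L) {
  simulate_mendelian_data(
    n_genes = n_genes, n_pathways = 10L, n_go_terms = 12L,
    embed_dim = 8L, seed = seed)
}

fast_config <- function(seed = 1L) {
  boost_config(n_estimators = 40L, max_depth = 3L, learning_rate = 0.15,
               seed = seed)
}
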