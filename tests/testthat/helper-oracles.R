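# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately use brute force / dense algorithms, never the
# package's own code paths.

# Exhaustive hypergeometric upper tail: enumerate every draw of size nb from
# a universe of size nn whose first na elements are the successes, and count
# draws with overlap >= q.
enum_overlap_pvalue <- function(nn, na, nb, q) {
  if (q == 0) return(1)
  draws <- combn(nn, nb)
  hits <- colSums(draws <= na)
  mean(hits >= q)
}

# Monte-Carlo probability that the order statistics of N iid uniforms are
# componentwise <= r (r sorted ascending). u_(i) <= r_i for all i is
# equivalent to: for every i, at least i of the N values are <= r_i.
mc_order_stat_prob <- function(r, n_draws = 1e6) {
  N <- length(r)
  U <- matrix(runif(n_draws * N), n_draws, N)
  ok <- rep(TRUE, n_draws)
  for (i in seq_len(N)) {
    ok <- ok & (rowSums(U <= r[i]) >= i)
  }
  p <- mean(ok)
  list(p = p, se = sqrt(p * (1 - p) / n_draws))
}

# Dense all-pairs shortest paths (Floyd-Warshall) on an adjacency matrix.
dense_sp <- function(adj) {
  n <- nrow(adj)
  D <- ifelse(adj > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

dense_mean_sp <- function(adj, labels, A, B) {
  D <- dense_sp(adj)
  dimnames(D) <- list(labels, labels)
  vals <- c()
  for (a in A) for (b in B) {
    if (a == b) next
    vals <- c(vals, D[a, b])
  }
  vals <- vals[is.finite(vals)]
  if (!length(vals)) NaN else mean(vals)
}

# Direct transliteration of the Match-style scoring definition, independent
# of the package's vectorized scanning path.
oracle_score <- function(freqs, info, window, positions) {
  bases <- c(A = 1, C = 2, G = 3, T = 4)
  b <- bases[strsplit(window, "")[[1]]]
  cur <- sum(info[positions] * freqs[cbind(b[positions], positions)])
  mn <- sum(info[positions] * apply(freqs[, positions, drop = FALSE], 2, min))
  mx <- sum(info[positions] * apply(freqs[, positions, drop = FALSE], 2, max))
  (cur - mn) / (mx - mn)
}

# Small expression fixture: values matrix built from a vector spec.
toy_expr <- function(values, genes, samples, groups) {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  expression_matrix(m, setNames(groups, samples))
}

# Chain ontology root <- t1 <- t2 with 4 genes: g1 -> t2, g2 -> t1,
# g3/g4 -> root. Hand ICs: t1 = -ln(2/4), t2 = -ln(1/4).
chain_ontology <- function() {
  ontology_annotation(
    terms = c("root", "t1", "t2"),
    parents = list(root = character(), t1 = "root", t2 = "t1"),
    gene2terms = list(g1 = "t2", g2 = "t1", g3 = "root", g4 = "root"))
}

# Two 6-cliques joined by a single bridge; high weight inside, low on the
# bridge. Returns the weighted igraph and the planted membership.
two_clique_graph <- function(w_in = 0.9, w_bridge = -0.5) {
  g1 <- paste0("a", 1:6); g2 <- paste0("b", 1:6)
  edges <- rbind(t(combn(g1, 2)), t(combn(g2, 2)), c("a1", "b1"))
  g <- igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE)
  igraph::E(g)$weight <- c(rep(w_in, 30), w_bridge)
  list(graph = g, membership = setNames(rep(1:2, each = 6), c(g1, g2)))
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
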