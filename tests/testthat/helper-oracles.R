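# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and igraph / phyper / p.adjust): set arithmetic
# for Tanimoto, Floyd-Warshall + pair-dependency counting for betweenness,
# direct combinatorial enumeration for the hypergeometric tail, and a
# literal step-up for Benjamini-Hochberg.

fp_from_bits <- function(bits, len) {
  v <- integer(len)
  v[bits] <- 1L
  v
}

# Tanimoto via explicit set operations on bit positions.
oracle_tanimoto <- function(a, b) {
  A <- which(a == 1L); B <- which(b == 1L)
  u <- length(union(A, B))
  if (u == 0) return(0)
  length(intersect(A, B)) / u
}

# Thresholded raw score as a plain loop over ligand rows.
oracle_raw_score <- function(query, ligands, thr) {
  total <- 0
  for (i in seq_len(nrow(ligands))) {
    tc <- oracle_tanimoto(query, ligands[i, ])
    if (tc > thr) total <- total + tc
  }
  total
}

# Unnormalized shortest-path betweenness (endpoints excluded, each
# unordered pair once) from an adjacency matrix: Floyd-Warshall distances,
# DP shortest-path counts, then the pair-dependency sum.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n); diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  nsp <- matrix(0, n, n); diag(nsp) <- 1
  reach <- which(is.finite(d) & d > 0, arr.ind = TRUE)
  ord <- reach[order(d[reach]), , drop = FALSE]
  for (r in seq_len(nrow(ord))) {
    s <- ord[r, 1]; t <- ord[r, 2]
    pred <- which(adj[, t] == 1 & d[s, ] == d[s, t] - 1)
    nsp[s, t] <- sum(nsp[s, pred])
  }
  bc <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(d[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t]) {
        bc[v] <- bc[v] + nsp[s, v] * nsp[v, t] / nsp[s, t]
      }
    }
  }
  bc
}

# Hypergeometric upper tail by direct enumeration of the pmf.
oracle_hypergeom_tail <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Literal Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (r in m:1) {
    running <- min(running, p[o[r]] * m / r)
    adj[o[r]] <- running
  }
  adj
}

random_graph <- function(n, p_edge) {
  adj <- matrix(0L, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p_edge) adj[i, j] <- adj[j, i] <- 1L
  }
  adj
}

igraph_from_adj <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- paste0("n", seq_len(nrow(adj)))
  g
}
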