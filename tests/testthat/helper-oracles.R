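# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's own code paths (and igraph):
# graphs are adjacency matrices, shortest paths come from hand-rolled BFS.

# random simple undirected graph as a 0/1 adjacency matrix
random_graph_adj <- function(n, p) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1, p)
  a <- a + t(a)
  dimnames(a) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
  a
}

adj_to_igraph <- function(a) {
  igraph::graph_from_adjacency_matrix(a, mode = "undirected")
}

# BFS distances from one source on an adjacency matrix
bf_bfs_dist <- function(a, s) {
  n <- nrow(a)
  d <- rep(Inf, n); d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(a[v, ] == 1)
      new <- nb[d[nb] == Inf]
      d[new] <- d[v] + 1
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  d
}

bf_degree <- function(a) rowSums(a)

bf_closeness <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(v) {
    d <- bf_bfs_dist(a, v)[-v]
    d <- d[is.finite(d)]
    if (length(d) == 0) 0 else 1 / mean(d)
  }, numeric(1))
}

bf_clustering <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(v) {
    nb <- which(a[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    e <- sum(a[nb, nb]) / 2
    2 * e / (k * (k - 1))
  }, numeric(1))
}

# exhaustive shortest-path counting for betweenness; per-component
# normalization by (N-1)(N-2)/2
bf_betweenness <- function(a) {
  n <- nrow(a)
  # count shortest paths between every ordered pair through BFS DAG DP
  nsp <- matrix(0, n, n)    # number of shortest s-t paths
  dmat <- t(vapply(seq_len(n), function(s) bf_bfs_dist(a, s), numeric(n)))
  for (s in seq_len(n)) {
    ord <- order(dmat[s, ])
    nsp[s, s] <- 1
    for (v in ord) {
      if (v == s || !is.finite(dmat[s, v])) next
      pred <- which(a[v, ] == 1 & dmat[s, ] == dmat[s, v] - 1)
      nsp[s, v] <- sum(nsp[s, pred])
    }
  }
  # component membership
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (v in seq_len(n)) {
    if (is.na(comp[v])) {
      cid <- cid + 1
      comp[is.finite(bf_bfs_dist(a, v))] <- cid
    }
  }
  bw <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    others <- setdiff(which(comp == comp[v]), v)
    if (length(others) >= 2) {
      prs <- utils::combn(others, 2)
      for (i in seq_len(ncol(prs))) {
        s <- prs[1, i]; t <- prs[2, i]
        if (nsp[s, t] > 0 &&
            dmat[s, v] + dmat[v, t] == dmat[s, t]) {
          tot <- tot + nsp[s, v] * nsp[v, t] / nsp[s, t]
        }
      }
    }
    nc <- sum(comp == comp[v])
    den <- (nc - 1) * (nc - 2) / 2
    bw[v] <- if (den > 0) tot / den else 0
  }
  bw
}

# triple-loop TOM evaluation
bf_tom <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    shared <- 0
    for (u in seq_len(n)) shared <- shared + a[i, u] * a[u, j]
    tom[i, j] <- (shared + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# random symmetric weighted adjacency in [0,1], zero diagonal
random_weighted_adj <- function(n) {
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- runif(n * (n - 1) / 2)
  a <- a + t(a)
  dimnames(a) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  a
}

# small count dataset from an explicit matrix
make_dataset <- function(counts, conditions = NULL) {
  n <- ncol(counts)
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("s%02d", 1:n)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(conditions)) {
    conditions <- rep(c("control", "salt"), length.out = n)
  }
  design <- data.frame(sample = colnames(counts), condition = conditions,
                       time_h = 0, replicate = seq_len(n))
  count_dataset(counts, design)
}
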