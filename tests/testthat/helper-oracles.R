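# Independent oracles used to cross-check the implementation.

# Betweenness by matrix powers: a walk of length d(s,t) is necessarily a
# shortest path, so sigma(s,t) = (A^d)[s,t] and the count through v splits
# multiplicatively at v. Pure matrix algebra, independent of Brandes.
bruteBetweenness <- function(adj) {
  n <- nrow(adj)
  pow <- list(diag(n), adj)  # pow[[L+1]] = A^L
  for (L in 2:max(n - 1, 2)) pow[[L + 1]] <- pow[[L]] %*% adj
  dist <- matrix(Inf, n, n); diag(dist) <- 0
  for (L in 1:(n - 1)) {
    newly <- pow[[L + 1]] > 0 & !is.finite(dist)
    dist[newly] <- L
  }
  sigma <- function(s, t) {
    d <- dist[s, t]
    if (!is.finite(d)) return(0)
    if (d == 0) return(1)
    pow[[d + 1]][s, t]
  }
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v) next
      dst <- dist[s, t]
      if (!is.finite(dst)) next
      dsv <- dist[s, v]; dvt <- dist[v, t]
      if (is.finite(dsv) && is.finite(dvt) && dsv + dvt == dst)
        bc[v] <- bc[v] + sigma(s, v) * sigma(v, t) / sigma(s, t)
    }
  }
  bc
}

# Plain two-sample equal-variance t-test, coded from the textbook formulas.
bruteTwoSampleT <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  tt <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, p = 2 * pt(-abs(tt), n1 + n2 - 2))
}

# Hypergeometric upper tail by explicit term summation over choose().
bruteHyperTail <- function(a, setSize, N, querySize) {
  ks <- a:min(setSize, querySize)
  sum(choose(setSize, ks) * choose(N - setSize, querySize - ks)) /
    choose(N, querySize)
}

# Independently coded vote count.
bruteVotes <- function(p, threshold = 0.05) {
  cnt <- 0L
  for (i in seq_along(p))
    if (!is.na(p[i]) && p[i] < threshold) cnt <- cnt + 1L
  cnt
}

# Random simple undirected graph as an adjacency matrix + edge data.frame.
randomGraphFixture <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  idx <- which(upper.tri(adj))
  on <- idx[runif(length(idx)) < p]
  adj[on] <- 1L
  adj <- adj + t(adj)
  nodes <- sprintf("n%02d", seq_len(n))
  dimnames(adj) <- list(nodes, nodes)
  ij <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  edges <- data.frame(protein1 = nodes[ij[, 1]], protein2 = nodes[ij[, 2]],
                      combined_score = rep(950L, nrow(ij)))
  list(adj = adj, edges = edges, nodes = nodes)
}

# Sparse background + planted 5-clique, for module recovery checks.
cliqueFixture <- function(seed = 99, nBackground = 100, pBackground = 0.05) {
  set.seed(seed)
  nodes <- sprintf("n%03d", seq_len(nBackground))
  clique <- nodes[1:5]
  idx <- t(combn(nodes, 2))
  inClique <- idx[, 1] %in% clique & idx[, 2] %in% clique
  keep <- inClique | runif(nrow(idx)) < pBackground
  data.frame(protein1 = idx[keep, 1], protein2 = idx[keep, 2],
             combined_score = 950L)
}
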