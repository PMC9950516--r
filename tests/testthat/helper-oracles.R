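# Independent brute-force oracles for graph metrics, deliberately naive:
# triangle enumeration over node triples and Floyd-Warshall shortest paths.

brute_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

brute_ncp <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]] == 1) tri <- tri + 1
      }
    }
    2 * tri / (k * (k - 1))
  }, numeric(1))
}

brute_eg <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- brute_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

brute_lp <- function(adj) {
  d <- brute_distances(adj)
  ut <- d[upper.tri(d)]
  if (all(!is.finite(ut))) return(NA_real_)
  mean(ut[is.finite(ut)])
}

brute_nle <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    brute_eg(adj[nb, nb, drop = FALSE])
  }, numeric(1))
}

random_adjacency <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj))
  adj[up] <- as.integer(runif(length(up)) < p)
  adj + t(adj)
}

path_graph <- function(n) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- 1L
  adj
}

complete_graph <- function(n) {
  adj <- matrix(1L, n, n)
  diag(adj) <- 0L
  adj
}
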