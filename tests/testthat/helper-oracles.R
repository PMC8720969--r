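# Independent oracles used across the suite. None of them share code paths
# with the package: betweenness comes from matrix powers of the adjacency
# matrix, hypergeometric tails from binomial-coefficient sums, and the GSEA
# enrichment score from a literal running-sum loop.

# Betweenness via walk counting: the number of shortest u-v paths equals the
# number of walks of minimal length, read off powers of the adjacency matrix;
# path counts through w follow from the composition rule
# sigma_uv(w) = sigma_uw * sigma_wv when d(u,w) + d(w,v) = d(u,v).
walkBetweenness <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  S <- matrix(0, n, n); diag(S) <- 1
  Ak <- diag(n)
  if (n > 1) for (k in seq_len(n - 1)) {
    Ak <- Ak %*% A
    newly <- is.infinite(D) & Ak > 0
    D[newly] <- k
    S[newly] <- Ak[newly]
  }
  bc <- numeric(n)
  for (w in seq_len(n)) for (u in seq_len(n)) for (v in seq_len(n)) {
    if (u < v && u != w && v != w && is.finite(D[u, v]) &&
        is.finite(D[u, w]) && is.finite(D[w, v]) &&
        D[u, w] + D[w, v] == D[u, v]) {
      bc[w] <- bc[w] + S[u, w] * S[w, v] / S[u, v]
    }
  }
  bc
}

# random named G(n, p) graph as a GeneNetwork plus its adjacency matrix
randomTestGraph <- function(n, p) {
  A <- matrix(0, n, n)
  if (n > 1) {
    pairs <- which(upper.tri(A), arr.ind = TRUE)
    on <- runif(nrow(pairs)) < p
    A[pairs[on, , drop = FALSE]] <- 1
    A <- A + t(A)
  }
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  list(net = GeneNetwork(g), A = A)
}

# hypergeometric upper tail from binomial coefficients
chooseTail <- function(k, K, n, N) {
  if (k <= 0) return(1)
  lo <- max(k, n - (N - K))
  hi <- min(K, n)
  if (lo > hi) return(0)
  sum(choose(K, lo:hi) * choose(N - K, n - (lo:hi))) / choose(N, n)
}

# literal running-sum enrichment score (scores must be sorted descending)
esLoop <- function(scores, hits, weight) {
  N <- length(scores); Nh <- sum(hits)
  wsum <- sum(abs(scores[hits])^weight)
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    run <- run + if (hits[i]) abs(scores[i])^weight / wsum else -1 / (N - Nh)
    if (abs(run) > abs(best)) best <- run
  }
  best
}
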