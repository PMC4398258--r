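# Independent oracles, kept deliberately separate from the package's
# code paths.

# upper-tail hypergeometric P(X >= k) by direct combinatorial summation
oracle_hyper_upper <- function(k, N, K, n) {
  lo <- max(0L, n - (N - K))
  hi <- min(K, n)
  if (k > hi) return(0)
  kk <- max(k, lo):hi
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

# two-sided Fisher p by enumeration of all tables with fixed margins
oracle_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  lo <- max(0L, c1 - (N - r1)); hi <- min(c1, r1)
  kk <- lo:hi
  probs <- exp(lchoose(c1, kk) + lchoose(N - c1, r1 - kk) - lchoose(N, r1))
  p_obs <- probs[kk == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# minimal dense reference MCL: no pruning, plain power iteration,
# clusters read from attractor rows
reference_mcl <- function(adj, inflation = 2.2, iters = 100) {
  diag(adj) <- 1
  M <- sweep(adj, 2, colSums(adj), "/")
  for (i in seq_len(iters)) {
    M <- M %*% M
    M <- M ^ inflation
    M <- sweep(M, 2, colSums(M), "/")
  }
  attractors <- which(diag(M) > 1e-6)
  clusters <- lapply(attractors, function(a) sort(which(M[a, ] > 1e-6)))
  unique(clusters[order(vapply(clusters, min, 0))])
}
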