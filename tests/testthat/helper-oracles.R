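# Independent brute-force oracles. These deliberately mirror the defining
# formulas with explicit loops and never call the package's own
# implementations.

# inner products of all column pairs, explicit double loop
innerprod_oracle <- function(s) {
  n <- ncol(s)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    out[i, j] <- sum(s[, i] * s[, j])
  }
  out
}

# min-max rescale each entry by explicit scans over row i and column j
minmax_oracle <- function(sp) {
  n <- nrow(sp)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    scope <- c(sp[i, ], sp[, j])
    out[i, j] <- (sp[i, j] - min(scope)) / (max(scope) - min(scope))
  }
  out
}

# Pearson correlation by the explicit covariance formula
pearson_oracle <- function(x) {
  n <- ncol(x)
  m <- nrow(x)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    xi <- x[, i] - mean(x[, i]); xj <- x[, j] - mean(x[, j])
    out[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  out
}

# topological overlap, verbatim triple loop over (i, j, u)
tom_oracle <- function(a) {
  n <- nrow(a)
  w <- matrix(0, n, n)
  k <- numeric(n)
  for (i in seq_len(n)) for (u in seq_len(n)) if (u != i) k[i] <- k[i] + a[i, u]
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { w[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    w[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  w
}

# hypergeometric tails by direct combinatorial sums
hyper_oracle <- function(N, K, n, k, direction) {
  pk <- function(x) choose(K, x) * choose(N - K, n - x) / choose(N, n)
  ks <- max(0L, n + K - N):min(n, K)
  if (direction == "over") sum(pk(ks[ks >= k])) else sum(pk(ks[ks <= k]))
}

# random symmetric adjacency in [0, 1] with zero diagonal
random_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n, n)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  diag(a) <- 0
  a
}

# random calibrated-style matrix: entries strictly in (0, 1)
random_calibrated <- function(m, n) {
  x <- matrix(stats::runif(m * n, 0.05, 0.95), m, n,
              dimnames = list(sprintf("s%d", 1:m), sprintf("g%d", 1:n)))
  class(x) <- c("CalibratedMatrix", "matrix", "array")
  x
}

# small raw expression fixture with gene/sample ids
random_expression <- function(m, n, seed = 1L) {
  set.seed(seed)
  expression_matrix(matrix(stats::runif(m * n, 1, 20), m, n,
                           dimnames = list(sprintf("s%d", 1:m),
                                           sprintf("g%d", 1:n))))
}
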