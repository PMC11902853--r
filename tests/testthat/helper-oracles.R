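# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately share no code with R/.

# Breadth-first-search hop distances on a 0/1 adjacency (row = source).
oracle_bfs_distances <- function(adj, directed = TRUE) {
  n <- nrow(adj)
  if (!directed) adj <- 1 * ((adj + t(adj)) > 0)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- integer(0)
      for (v in frontier) nxt <- c(nxt, which(adj[v, ] == 1))
      nxt <- unique(nxt[!is.finite(d[s, nxt])])
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

# Mean inverse distance over ordered pairs (1/Inf = 0).
oracle_global_efficiency <- function(adj, directed = TRUE) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- oracle_bfs_distances(adj, directed)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
  tot / (n * (n - 1))
}

# Fagiolo directed clustering by explicit triangle-motif enumeration:
# count ordered triples (j, k) such that edges i~j, i~k, j~k close a
# directed triangle in any motif orientation. Equivalent to
# [(A+A')^3]_ii / 2 by enumeration rather than matrix powers.
oracle_directed_clustering <- function(adj) {
  n <- nrow(adj)
  S <- adj + t(adj)
  vapply(seq_len(n), function(i) {
    tri <- 0
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j == i || k == i || j == k) next
      tri <- tri + S[i, j] * S[j, k] * S[k, i]
    }
    dtot <- sum(adj[i, ]) + sum(adj[, i])
    dbi <- sum(adj[i, ] * adj[, i])
    den <- 2 * (dtot * (dtot - 1) - 2 * dbi)
    if (den > 0) tri / den else 0
  }, numeric(1))
}

# Least-squares AR fit via explicitly assembled normal equations.
# Returns the ML residual variance of `target` regressed on `p` lags of
# each row of `sources` (a matrix whose columns are time).
oracle_lag_regression_var <- function(target_row, sources, p) {
  N <- length(target_row)
  ne <- N - p
  y <- target_row[(p + 1):N]
  X <- NULL
  for (j in seq_len(nrow(sources))) for (k in seq_len(p))
    X <- cbind(X, sources[j, (p + 1 - k):(N - k)])
  beta <- solve(t(X) %*% X, t(X) %*% y)
  r <- y - X %*% beta
  sum(r^2) / ne
}

# Full pairwise Granger matrix via the explicit regression oracle.
oracle_granger <- function(x, p) {
  n <- nrow(x)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    sig_red <- oracle_lag_regression_var(x[i, ], x[i, , drop = FALSE], p)
    for (y in seq_len(n)) {
      if (y == i) next
      sig_full <- oracle_lag_regression_var(x[i, ], x[c(i, y), , drop = FALSE], p)
      W[y, i] <- log(sig_red / sig_full)
    }
  }
  W
}

# Stationary covariance of a VAR via the companion-form recursion
# Gamma <- A Gamma A' + Sigma_c, iterated to convergence.
oracle_stationary_cov <- function(coeffs, noise_cov, tol = 1e-12,
                                  max_iter = 10000) {
  p <- length(coeffs)
  n <- nrow(coeffs[[1]])
  Ac <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) Ac[seq_len(n), (k - 1) * n + seq_len(n)] <- coeffs[[k]]
  if (p > 1) Ac[n + seq_len(n * (p - 1)), seq_len(n * (p - 1))] <-
      diag(n * (p - 1))
  Sc <- matrix(0, n * p, n * p)
  Sc[seq_len(n), seq_len(n)] <- noise_cov
  G <- Sc
  for (it in seq_len(max_iter)) {
    G2 <- Ac %*% G %*% t(Ac) + Sc
    if (max(abs(G2 - G)) < tol) break
    G <- G2
  }
  G2[seq_len(n), seq_len(n)]
}

# Seeded random binary network (directed or undirected).
random_binary_network <- function(n, p_edge = 0.3, directed = TRUE,
                                  seed = 1) {
  set.seed(seed)
  adj <- matrix(as.integer(stats::runif(n * n) < p_edge), n, n)
  diag(adj) <- 0L
  if (!directed) adj <- 1L * ((adj + t(adj)) > 0)
  binary_network(adj, directed)
}

# Small helper: roi_ts from a plain matrix.
ts_of <- function(m, rate = 500) roi_timeseries(m, sampling_rate_hz = rate)
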