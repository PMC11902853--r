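test_that("fit_var matches the brute-force normal equations and recovers AR gains", {
  # oracle agreement on a 3 x 200 series
  sp <- random_mvar_spec(3, 2, n_edges = 3, seed = 13, n_samples = 200)
  ts <- zscore(simulate_mvar(sp))
  fit <- fit_var(ts, 2)
  for (i in 1:3) {
    y <- ts$data[i, 3:200]
    X <- cbind(ts$data[1, 2:199], ts$data[1, 1:198],
               ts$data[2, 2:199], ts$data[2, 1:198],
               ts$data[3, 2:199], ts$data[3, 1:198])
    beta <- solve(t(X) %*% X, t(X) %*% y)
    got <- c(fit$coeff_matrices[[1]][i, 1], fit$coeff_matrices[[2]][i, 1],
             fit$coeff_matrices[[1]][i, 2], fit$coeff_matrices[[2]][i, 2],
             fit$coeff_matrices[[1]][i, 3], fit$coeff_matrices[[2]][i, 3])
    expect_equal(got, as.numeric(beta), tolerance = 1e-10)
  }
  expect_equal(fit$n_effective, 198)

  # AR(1) coefficient recovery
  sp1 <- simulation_spec(1, 1, list(matrix(0.5)), n_samples = 5000, seed = 2)
  f1 <- fit_var(simulate_mvar(sp1), 1)
  expect_equal(f1$coeff_matrices[[1]][1, 1], 0.5, tolerance = 0.05)

  # independent white noise: cross coefficients near zero
  spw <- simulation_spec(2, 1, list(matrix(0, 2, 2)), n_samples = 5000,
                         seed = 3)
  fw <- fit_var(simulate_mvar(spw), 1)
  expect_true(all(abs(fw$coeff_matrices[[1]][cbind(c(1, 2), c(2, 1))]) <
                    4 / sqrt(5000)))

  # duplicated channel: rank-deficient design rejected
  dup <- ts
  dup$data[2, ] <- dup$data[1, ]
  expect_error(fit_var(dup, 2), "rank-deficient")
})

test_that("BIC order selection recovers generating orders and breaks ties low", {
  # white noise prefers order 1 (complexity penalty)
  hits <- vapply(1:20, function(s) {
    spw <- simulation_spec(3, 1, list(matrix(0, 3, 3)), n_samples = 400,
                           seed = s)
    as.integer(select_order_bic(simulate_mvar(spw), 1, 6)) == 1L
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  # MVAR(2) recovery (modal over 20 seeds)
  sel2 <- vapply(1:20, function(s) {
    sp <- random_mvar_spec(5, 2, n_edges = 8, seed = 17, n_samples = 600)
    as.integer(select_order_bic(simulate_mvar(sp, seed = s), 1, 6))
  }, integer(1))
  expect_equal(as.integer(names(which.max(table(sel2)))), 2L)

  # MVAR(5) recovery at the full candidate range
  sel5 <- vapply(1:20, function(s) {
    as.integer(select_order_bic(simulate_mvar(mvar5_demo_spec(), seed = s),
                                1, 10))
  }, integer(1))
  expect_equal(as.integer(names(which.max(table(sel5)))), 5L)

  # singleton candidate set
  ts <- simulate_mvar(random_mvar_spec(3, 1, seed = 1, n_samples = 300))
  expect_equal(as.integer(select_order_bic(ts, 3, 3)), 3L)
})

test_that("pairwise GC matches theory and the regression oracle, and is nonnegative", {
  # independent channels: both F below 0.01
  spw <- simulation_spec(2, 1, list(matrix(0, 2, 2)), n_samples = 10000,
                         seed = 5)
  Ww <- granger_pairwise(zscore(simulate_mvar(spw)), 1)$weights
  expect_lt(max(Ww), 0.01)

  # closed form: x_t = 0.9 y_{t-1} + e -> F(y->x) = ln(1.81)
  set.seed(8)
  n <- 20000
  y <- rnorm(n)
  x <- c(0, 0.9 * y[-n]) + rnorm(n)
  W <- granger_pairwise(zscore(ts_of(rbind(x, y))), 1)$weights
  expect_lt(abs(W[2, 1] - log(1.81)), 0.03)
  expect_lt(W[1, 2], 0.01)
  # asymmetry for the coupled pair
  expect_gt(W[2, 1], 10 * W[1, 2])

  # oracle agreement on a 4 x 300 series
  sp <- random_mvar_spec(4, 2, n_edges = 5, seed = 23, n_samples = 300)
  ts <- zscore(simulate_mvar(sp))
  expect_equal(granger_pairwise(ts, 2)$weights, oracle_granger(ts$data, 2),
               tolerance = 1e-9)

  # nonnegativity on many random series
  for (s in 1:5) {
    sp <- random_mvar_spec(5, 2, n_edges = 6, seed = s, n_samples = 200)
    W <- granger_pairwise(zscore(simulate_mvar(sp)), 3)$weights
    expect_true(all(W >= 0))
  }
})

test_that("Pearson matrices match the direct formula, are symmetric and bounded", {
  set.seed(41)
  ts <- ts_of(matrix(rnorm(5 * 200), 5))
  P <- pearson_matrix(ts)
  expect_false(P$directed)
  expect_equal(P$weights, t(P$weights))
  expect_true(all(abs(P$weights) <= 1))
  expect_true(all(diag(P$weights) == 0))
  # entrywise direct covariance/sigma computation
  for (i in 1:4) for (j in (i + 1):5) {
    a <- ts$data[i, ]; b <- ts$data[j, ]
    rho <- mean((a - mean(a)) * (b - mean(b))) /
      (sqrt(mean((a - mean(a))^2)) * sqrt(mean((b - mean(b))^2)))
    expect_equal(P$weights[i, j], rho, tolerance = 1e-12)
  }
  # affine relation: rho(x, 2x+3) = 1; rho(x, -x) = -1
  m <- rbind(ts$data[1, ], 2 * ts$data[1, ] + 3, -ts$data[1, ])
  P2 <- pearson_matrix(ts_of(m))
  expect_equal(P2$weights[1, 2], 1)
  expect_equal(P2$weights[1, 3], -1)
  # constant row rejected
  bad <- ts
  bad$data[4, ] <- 2
  expect_error(pearson_matrix(bad), "constant")
})

test_that("weight normalization rectifies, scales to max 1 and is idempotent", {
  w <- matrix(c(0, 4, 2, 0), 2)
  W <- conn_matrix(w, "GCA")
  N <- normalize_weights(W)
  expect_equal(N$weights, matrix(c(0, 1, 0.5, 0), 2))
  expect_equal(normalize_weights(N)$weights, N$weights)
  # PCC: absolute value first
  pw <- matrix(0, 3, 3)
  pw[1, 2] <- pw[2, 1] <- -0.8
  pw[1, 3] <- pw[3, 1] <- 0.4
  NP <- normalize_weights(conn_matrix(pw, "PCC"))
  expect_equal(NP$weights[1, 2], 1)
  expect_equal(NP$weights[1, 3], 0.5)
  expect_error(normalize_weights(conn_matrix(matrix(0, 2, 2), "GCA")),
               "all-zero")
})

test_that("average connection strength uses the documented pair conventions", {
  w <- matrix(0.5, 3, 3); diag(w) <- 0
  expect_equal(average_connection_strength(conn_matrix(w, "GCA")), 0.5)
  # single nonzero entry in a directed 3-node matrix: 1/6
  w2 <- matrix(0, 3, 3); w2[1, 2] <- 1
  expect_equal(average_connection_strength(conn_matrix(w2, "GCA")), 1 / 6)
  # permutation invariance
  set.seed(6)
  w3 <- matrix(runif(16), 4); diag(w3) <- 0
  perm <- c(3, 1, 4, 2)
  expect_equal(average_connection_strength(conn_matrix(w3, "GCA")),
               average_connection_strength(conn_matrix(w3[perm, perm],
                                                       "GCA")))
})

test_that("epoch aggregation is the elementwise mean over matching matrices", {
  w1 <- matrix(0, 3, 3); w2 <- matrix(1, 3, 3); diag(w2) <- 0
  m1 <- conn_matrix(w1, "GCA"); m2 <- conn_matrix(w2, "GCA")
  expect_equal(aggregate_epochs(list(m2, m2))$weights, w2)
  expect_equal(aggregate_epochs(list(m1, m2))$weights, w2 / 2)
  # brute-force mean over 5 random matrices
  set.seed(12)
  ms <- lapply(1:5, function(i) {
    w <- matrix(runif(9), 3); diag(w) <- 0
    conn_matrix(w, "GCA")
  })
  expect_equal(aggregate_epochs(ms)$weights,
               Reduce(`+`, lapply(ms, `[[`, "weights")) / 5)
  bad <- conn_matrix(matrix(0, 4, 4), "GCA")
  expect_error(aggregate_epochs(list(m1, bad)), "share")
})
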