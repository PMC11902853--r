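rand_norm_mat <- function(n, seed, labels = paste0("R", seq_len(n))) {
  set.seed(seed)
  w <- matrix(runif(n * n), n); diag(w) <- 0
  normalize_weights(conn_matrix(w, "GCA", region_labels = labels))
}

test_that("group mean matrices equal the brute-force elementwise mean", {
  ms <- lapply(1:5, rand_norm_mat, n = 6)
  expect_equal(group_mean_matrix(ms)$weights,
               Reduce(`+`, lapply(ms, `[[`, "weights")) / 5)
  expect_equal(group_mean_matrix(ms[2])$weights, ms[[2]]$weights)
  w0 <- conn_matrix(matrix(0, 6, 6), "GCA")
  one <- ms[[1]]
  expect_equal(group_mean_matrix(list(w0, one))$weights, one$weights / 2)
  bad <- rand_norm_mat(4, 1)
  expect_error(group_mean_matrix(list(ms[[1]], bad)), "shape")
})

test_that("top connections are the brute-force strongest edges with stable ties", {
  W <- rand_norm_mat(10, 3)
  top <- top_connections(W, 20)
  # brute-force sort of all off-diagonal entries
  w <- W$weights
  off <- which(row(w) != col(w))
  ord <- off[order(-w[off])]
  expect_equal(top$strength, w[ord[1:20]])
  expect_equal(top$source[1],
               W$region_labels[(ord[1] - 1) %% 10 + 1])
  # k = 1: the unique max entry
  expect_equal(top_connections(W, 1)$strength, max(w))
  # permuting labels preserves the selected strengths
  perm <- c(5, 1, 7, 2, 9, 3, 10, 4, 8, 6)
  Wp <- conn_matrix(w[perm, perm], "GCA",
                    region_labels = W$region_labels[perm],
                    normalized = TRUE)
  expect_equal(top_connections(Wp, 20)$strength, top$strength)
  expect_warning(tc <- top_connections(rand_norm_mat(3, 1), 20), "exceeds")
  expect_equal(nrow(tc), 6)
})

test_that("dissimilar connections rank |delta| keeping the sign, antisymmetrically", {
  A <- rand_norm_mat(8, 11)
  B <- rand_norm_mat(8, 12)
  gdc <- dissimilar_connections(A, B, 20)
  D <- A$weights - B$weights
  off <- which(row(D) != col(D))
  expect_equal(gdc$abs_delta, sort(abs(D[off]), decreasing = TRUE)[1:20])
  # identical groups: all deltas zero
  z <- dissimilar_connections(A, A, 5)
  expect_true(all(z$delta == 0))
  # single perturbed entry ranks first with positive sign
  P <- A
  P$weights[2, 5] <- min(1, P$weights[2, 5] + 0.5)
  d1 <- dissimilar_connections(P, A, 3)
  expect_equal(d1$source[1], "R2")
  expect_equal(d1$target[1], "R5")
  expect_gt(d1$delta[1], 0)
  # swapping inputs flips every sign, same edges
  fwd <- dissimilar_connections(A, B, 10)
  rev <- dissimilar_connections(B, A, 10)
  expect_equal(fwd$source, rev$source)
  expect_equal(fwd$delta, -rev$delta)
})

test_that("out-strength rankings equal brute-force row sums", {
  W <- rand_norm_mat(9, 21)
  r <- out_strength_ranking(W, 5)
  s <- rowSums(W$weights)
  expect_equal(r$out_strength, sort(s, decreasing = TRUE)[1:5])
  # one dominant row
  w1 <- matrix(0, 4, 4); w1[3, -3] <- 1
  W1 <- conn_matrix(w1, "GCA")
  expect_equal(out_strength_ranking(W1, 1)$region, "R3")
  # k = n returns all regions in order
  expect_equal(out_strength_ranking(W, 9)$out_strength,
               sort(s, decreasing = TRUE))
  # dissimilarity: a uniform +0.1 row difference ranks that region first
  P <- W
  P$weights[4, -4] <- P$weights[4, -4] + 0.1
  gd <- out_strength_dissimilarity(P, W, 2)
  expect_equal(gd$region[1], "R4")
  expect_equal(gd$delta[1], 0.8, tolerance = 1e-12)
  expect_true(all(out_strength_dissimilarity(W, W, 3)$delta == 0))
  # undirected input rejected
  und <- normalize_weights(pearson_matrix(ts_of(matrix(rnorm(4 * 50), 4))))
  expect_error(out_strength_ranking(und), "directed")
})

test_that("hub consensus counts list appearances once per list", {
  lcs <- data.frame(source = c("A", "B"), target = c("B", "C"))
  gdc <- data.frame(source = "A", target = "D")
  hodr <- data.frame(region = c("A", "E"))
  gdr <- data.frame(region = "B")
  rep <- hub_consensus(lcs, gdc, hodr, gdr)
  freq <- setNames(rep$frequency$frequency, rep$frequency$region)
  expect_equal(freq[["A"]], 3)  # lcs + gdc + hodr
  expect_equal(freq[["B"]], 2)  # lcs (once, despite two appearances) + gdr
  expect_equal(freq[["E"]], 1)
  expect_setequal(rep$hubs, c("A", "B"))
  # brute-force membership count on random lists
  set.seed(2)
  regs <- paste0("R", 1:12)
  l1 <- data.frame(source = sample(regs, 6), target = sample(regs, 6))
  l2 <- data.frame(source = sample(regs, 6), target = sample(regs, 6))
  h1 <- data.frame(region = sample(regs, 4))
  h2 <- data.frame(region = sample(regs, 4))
  rep2 <- hub_consensus(l1, l2, h1, h2)
  for (i in seq_len(nrow(rep2$frequency))) {
    r <- rep2$frequency$region[i]
    manual <- (r %in% c(l1$source, l1$target)) +
      (r %in% c(l2$source, l2$target)) + (r %in% h1$region) +
      (r %in% h2$region)
    expect_equal(rep2$frequency$frequency[i], manual)
  }
})

test_that("regions carrying planted effects reach consensus hub status", {
  # all effect edges emanate from 3 designated source regions
  base <- random_mvar_spec(10, 2, n_edges = 6, seed = 31, n_samples = 400)
  ee <- cbind(c(1, 1, 2, 2, 3, 3), c(4, 5, 6, 7, 8, 9))
  hits <- vapply(1:20, function(r) {
    cd <- make_cohort(cohort_spec(6, 6, base, ee, effect_gain = 0.3,
                                  seed = r))
    W <- cohort_connectivity(cd, "GCA", order = 2)
    g <- cd$manifest$group
    Wp <- group_mean_matrix(W[g == "TLE"])
    Wc <- group_mean_matrix(W[g == "HC"])
    rep <- hub_consensus(top_connections(Wp, 10),
                         dissimilar_connections(Wp, Wc, 10),
                         out_strength_ranking(Wp, 3),
                         out_strength_dissimilarity(Wp, Wc, 3))
    freq <- setNames(rep$frequency$frequency, rep$frequency$region)
    all(c("R1", "R2", "R3") %in% names(freq)) &&
      all(freq[c("R1", "R2", "R3")] >= 2)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("hub reports serialize to JSON and CSV", {
  dir <- withr::local_tempdir()
  W <- rand_norm_mat(8, 41)
  rep <- hub_consensus(top_connections(W, 10),
                       dissimilar_connections(W, rand_norm_mat(8, 42), 10),
                       out_strength_ranking(W, 3),
                       out_strength_dissimilarity(W, rand_norm_mat(8, 43),
                                                  3))
  write_hub_report(rep, dir)
  expect_true(file.exists(file.path(dir, "hubs.json")))
  parsed <- jsonlite::read_json(file.path(dir, "hubs.json"))
  expect_equal(unlist(parsed$hubs), rep$hubs)
  expect_true(file.exists(file.path(dir, "hubs_lcs.csv")))
})
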