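test_that("normality-gated tests choose the right branch and p-values", {
  # identical samples: maximal overlap, p = 1 under the U test
  a <- c(1.2, 5.3, 2.2, 8.1, 0.4, 3.3)
  res <- normality_gated_test(a, a)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  expect_equal(res$direction, 0)

  # complete separation, 10 vs 10, no ties: exact U tail 2 / choose(20, 10).
  # The skewed sample (outlier) fails the K-S gate, forcing the U branch.
  x <- c(1:9, 1000) + 0.1
  y <- c(2001:2010) + 0.3
  res2 <- normality_gated_test(x, y)
  expect_equal(res2$test_used, "Mann-Whitney U")
  expect_equal(res2$p_value, 2 / choose(20, 10), tolerance = 1e-10)
  expect_equal(res2$direction, -1)

  # Gaussian samples pass the gate and get a t-test
  set.seed(5)
  res3 <- normality_gated_test(rnorm(40), rnorm(40))
  expect_equal(res3$test_used, "t-test")

  # zero-variance sample forces the U branch with a warning
  expect_warning(res4 <- normality_gated_test(rep(1, 5), c(2, 3, 4, 5, 6)),
                 "zero-variance")
  expect_equal(res4$test_used, "Mann-Whitney U")

  expect_error(normality_gated_test(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("type-I error of the gated test is near the nominal level", {
  set.seed(99)
  rejections <- vapply(1:200, function(i) {
    normality_gated_test(rnorm(30), rnorm(30))$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.05)
})

test_that("feature screening keeps separated features and respects alpha", {
  set.seed(17)
  n <- 40
  labels <- rep(c("HC", "TLE"), each = n / 2)
  feats <- matrix(rnorm(n * 30), n)
  colnames(feats) <- paste0("f", 1:30)
  feats[labels == "TLE", 1] <- feats[labels == "TLE", 1] + 10  # separated
  mask <- select_features(feats, labels)
  expect_true(mask[1])
  # null features selected at roughly the alpha rate over replicates
  rates <- vapply(1:20, function(r) {
    set.seed(1000 + r)
    f0 <- matrix(rnorm(n * 50), n)
    mean(select_features(f0, labels))
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.04)
  # alpha = 0 empties the mask and classification aborts
  expect_false(any(select_features(feats, labels, alpha = 0)))
  expect_error(classify_cohort(feats, labels, alpha = 0), "screen")
  # BH correction is monotone: never selects more than uncorrected
  m_bh <- select_features(feats, labels, correction = "BH")
  expect_lte(sum(m_bh), sum(mask))
})

test_that("stratified splits reproduce the 34/14 arithmetic and determinism", {
  labels <- rep(c("TLE", "HC"), c(34, 14))
  part <- split_stratified(labels, 0.7, seed = 3)
  expect_equal(sum(labels[part$train] == "TLE"), 24)
  expect_equal(sum(labels[part$train] == "HC"), 10)
  expect_equal(sum(labels[part$validation] == "TLE"), 10)
  expect_equal(sum(labels[part$validation] == "HC"), 4)
  expect_setequal(c(part$train, part$validation), seq_along(labels))
  # determinism
  expect_identical(part, split_stratified(labels, 0.7, seed = 3))
  expect_false(identical(part$train,
                         split_stratified(labels, 0.7, seed = 4)$train))
  # boundary fractions rejected
  expect_error(split_stratified(labels, 1), "train_frac")
  expect_error(split_stratified(labels, 0), "train_frac")
  expect_error(split_stratified(rep("A", 10), 0.7), "2 classes")
})

test_that("SVM evaluation is perfect on separable clusters and null under permutation", {
  set.seed(23)
  n <- 60
  labels <- rep(c("HC", "TLE"), each = n / 2)
  feats <- matrix(rnorm(n * 4, sd = 0.1), n)
  feats[labels == "TLE", ] <- feats[labels == "TLE", ] + 3
  part <- split_stratified(labels, 0.7, seed = 1)
  rep1 <- train_eval_svm(feats, labels, part, seed = 1)
  expect_equal(rep1$accuracy, 1)
  expect_equal(rep1$kappa, 1)
  expect_equal(rep1$roc_auc, 1)
  expect_equal(rep1$f1, 1)
  # permuted labels: mean AUC near 0.5 over replicates
  aucs <- vapply(1:20, function(r) {
    set.seed(3000 + r)
    lp <- sample(labels)
    p <- split_stratified(lp, 0.7, seed = r)
    train_eval_svm(feats, lp, p, seed = r)$roc_auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.12)
})

test_that("metric identities hold on imperfect classifiers", {
  set.seed(71)
  n <- 80
  labels <- rep(c("HC", "TLE"), each = n / 2)
  feats <- matrix(rnorm(n * 3), n)
  feats[labels == "TLE", 1] <- feats[labels == "TLE", 1] + 1  # weak signal
  part <- split_stratified(labels, 0.7, seed = 2)
  rep1 <- train_eval_svm(feats, labels, part, seed = 2)
  cm <- rep1$confusion
  nv <- sum(cm)
  # f1 from precision/recall
  expect_equal(rep1$f1,
               2 * rep1$precision * rep1$recall /
                 (rep1$precision + rep1$recall))
  # kappa from the contingency closed form
  po <- (cm["tp"] + cm["tn"]) / nv
  pe <- ((cm["tp"] + cm["fp"]) * (cm["tp"] + cm["fn"]) +
           (cm["fn"] + cm["tn"]) * (cm["fp"] + cm["tn"])) / nv^2
  expect_equal(rep1$kappa, unname((po - pe) / (1 - pe)))
  expect_true(rep1$roc_auc >= 0 && rep1$roc_auc <= 1)
  # AUC invariant to monotone transforms of the features
  rep2 <- train_eval_svm(feats * 3 + 1, labels, part, seed = 2)
  expect_equal(rep2$roc_auc, rep1$roc_auc)
})

test_that("training-only screening and standardization never touch validation rows", {
  set.seed(12)
  n <- 40
  labels <- rep(c("HC", "TLE"), each = n / 2)
  feats <- matrix(rnorm(n * 20), n)
  feats[labels == "TLE", 1:3] <- feats[labels == "TLE", 1:3] + 2
  part <- split_stratified(labels, 0.7, seed = 9)
  mask_clean <- select_features(feats, labels, rows = part$train)
  poisoned <- feats
  poisoned[part$validation, ] <- NaN
  mask_poisoned <- select_features(poisoned, labels, rows = part$train)
  expect_identical(mask_clean, mask_poisoned)
  expect_identical(attr(mask_clean, "p_values"),
                   attr(mask_poisoned, "p_values"))
})

test_that("the order sweep emits one row per order and is reproducible", {
  cd <- make_cohort(demo_cohort_spec(seed = 5, n_group_a = 6,
                                     n_group_b = 8, n_samples = 400))
  sw <- order_sweep(cd, orders = c(2, 5), seed = 11)
  expect_equal(sw$order, c(2, 5))
  expect_true(all(c("selected_psw", "n_features", "roc_auc") %in%
                    names(sw)))
  sw2 <- order_sweep(cd, orders = c(2, 5), seed = 11)
  expect_identical(sw, sw2)
  # single order: single row
  expect_equal(nrow(order_sweep(cd, orders = 5, seed = 11)), 1)
})
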