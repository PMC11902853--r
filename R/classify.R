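# Group statistics, Mann-Whitney feature screening, stratified splitting,
# linear-SVM classification and the lag-order sweep.

#' Normality-gated two-sample test
#'
#' Each sample is checked for normality with a one-sample
#' Kolmogorov-Smirnov test against a normal with the sample's own mean and
#' standard deviation. If both samples pass at `alpha`, an unpaired
#' two-sided t-test is used; otherwise a two-sided Mann-Whitney U test
#' (exact when both samples have at most 20 observations and no ties,
#' normal approximation with tie/continuity correction otherwise). A
#' zero-variance sample forces the Mann-Whitney branch with a warning.
#'
#' @param sample_a,sample_b numeric vectors with at least 3 observations;
#'   by convention `sample_a` is the patient group for the reported
#'   direction.
#' @param alpha normality-gate level (default 0.05).
#' @param feature_name label carried into the result.
#' @return A one-row data frame: feature_name, test_used, statistic,
#'   p_value, direction (sign of the a-minus-b median difference).
#' @export
normality_gated_test <- function(sample_a, sample_b, alpha = 0.05,
                                 feature_name = "") {
  if (length(sample_a) < 3 || length(sample_b) < 3)
    stop("both samples need at least 3 observations", call. = FALSE)
  degenerate <- stats::sd(sample_a) == 0 || stats::sd(sample_b) == 0
  if (degenerate)
    warning("zero-variance sample: using Mann-Whitney U", call. = FALSE)
  normal_ok <- function(x) {
    p <- suppressWarnings(
      stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
    p > alpha
  }
  use_t <- !degenerate && normal_ok(sample_a) && normal_ok(sample_b)
  if (use_t) {
    ht <- stats::t.test(sample_a, sample_b, var.equal = TRUE)
    test_used <- "t-test"
  } else {
    exact <- max(length(sample_a), length(sample_b)) <= 20 &&
      !any(duplicated(c(sample_a, sample_b)))
    ht <- suppressWarnings(
      stats::wilcox.test(sample_a, sample_b, exact = exact, correct = TRUE))
    test_used <- "Mann-Whitney U"
  }
  data.frame(feature_name = feature_name, test_used = test_used,
             statistic = unname(ht$statistic), p_value = ht$p.value,
             direction = sign(stats::median(sample_a) -
                                stats::median(sample_b)),
             stringsAsFactors = FALSE)
}

#' Normality-gated tests for every feature column
#'
#' @param features subjects x features numeric matrix (named columns).
#' @param labels group labels, one per row.
#' @param patient_group label treated as `sample_a` (default: the less
#'   frequent... the second factor level).
#' @param alpha gate level.
#' @return A data frame, one row per feature.
#' @export
group_test_table <- function(features, labels,
                             patient_group = levels(factor(labels))[2],
                             alpha = 0.05) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  a <- features[labels == patient_group, , drop = FALSE]
  b <- features[labels != patient_group, , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(ncol(features)), function(j)
    normality_gated_test(a[, j], b[, j], alpha,
                         colnames(features)[j] %||% paste0("f", j))))
  rownames(out) <- NULL
  out
}

#' Screen features by Mann-Whitney U test
#'
#' Keeps features whose two-sided U-test p-value between the two groups is
#' below `alpha`, with no multiple-testing correction by default. By
#' default only the rows in `rows` (e.g. the training partition) are used,
#' so the screen leaks no validation information; passing `rows = NULL`
#' screens on all subjects.
#'
#' @param features subjects x features matrix.
#' @param labels group labels per row.
#' @param alpha selection level (default 0.05).
#' @param rows integer indices of rows to screen on (default all).
#' @param correction `"none"` (default) or `"BH"` for Benjamini-Hochberg.
#' @return A logical mask over columns, with attribute `"p_values"`.
#' @export
select_features <- function(features, labels, alpha = 0.05, rows = NULL,
                            correction = c("none", "BH")) {
  correction <- match.arg(correction)
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  if (is.null(rows)) rows <- seq_len(nrow(features))
  x <- features[rows, , drop = FALSE]
  g <- factor(labels[rows])
  if (nlevels(g) != 2) stop("exactly two groups required", call. = FALSE)
  pv <- vapply(seq_len(ncol(x)), function(j) {
    a <- x[g == levels(g)[1], j]
    b <- x[g == levels(g)[2], j]
    if (stats::sd(c(a, b)) == 0) return(1)
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                        correct = TRUE)$p.value)
  }, numeric(1))
  if (correction == "BH") pv <- stats::p.adjust(pv, "BH")
  structure(pv < alpha, p_values = pv)
}

#' Stratified train/validation split
#'
#' Assigns `round(train_frac * class size)` subjects of each class to the
#' training partition (randomized by seed) and the rest to validation.
#' With 34 patients and 14 controls at 0.7 this yields 24 + 10 training
#' and 10 + 4 validation subjects.
#'
#' @param labels group labels; at least 2 classes of at least 2 members.
#' @param train_frac training fraction in (0, 1) (default 0.7).
#' @param seed RNG seed.
#' @return A list with integer index vectors `train` and `validation`.
#' @export
split_stratified <- function(labels, train_frac = 0.7, seed = 1L) {
  g <- factor(labels)
  if (nlevels(g) < 2) stop("need at least 2 classes", call. = FALSE)
  if (any(table(g) < 2)) stop("each class needs >= 2 members", call. = FALSE)
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must be in (0, 1)", call. = FALSE)
  train <- with_seed(seed, {
    unlist(lapply(levels(g), function(lv) {
      idx <- which(g == lv)
      n_tr <- round(train_frac * length(idx))
      if (n_tr < 1 || n_tr >= length(idx))
        stop(sprintf("class '%s' would have an empty partition", lv),
             call. = FALSE)
      sort(sample(idx, n_tr))
    }), use.names = FALSE)
  })
  train <- sort(train)
  list(train = train, validation = setdiff(seq_along(labels), train))
}

#' Train a linear SVM and evaluate it on the validation partition
#'
#' Features are standardized with training-set means and standard
#' deviations only; an SVM (linear kernel, unit cost by default) is trained
#' on the training rows and evaluated on the validation rows. Reported
#' metrics: accuracy, precision, recall (sensitivity), F1, Cohen's kappa
#' and ROC-AUC from the decision-function score.
#'
#' @param features subjects x features matrix (already screened).
#' @param labels group labels per row.
#' @param partition list with `train` and `validation` indices, as from
#'   [split_stratified()].
#' @param seed RNG seed (the linear fit is deterministic; kept for
#'   provenance and non-linear kernels).
#' @param positive label of the positive (patient) class; default the
#'   second factor level.
#' @param kernel,cost SVM kernel and regularization (defaults `"linear"`,
#'   1).
#' @return An object of class `classification_report` (a named list).
#' @export
train_eval_svm <- function(features, labels, partition, seed = 1L,
                           positive = NULL, kernel = "linear", cost = 1) {
  features <- as.matrix(features)
  g <- factor(labels)
  if (nlevels(g) != 2) stop("exactly two classes required", call. = FALSE)
  positive <- positive %||% levels(g)[2]
  if (!positive %in% levels(g)) stop("unknown positive class", call. = FALSE)
  negative <- setdiff(levels(g), positive)
  tr <- partition$train; va <- partition$validation
  if (length(unique(g[tr])) != 2 || length(unique(g[va])) != 2)
    stop("both classes must appear in both partitions", call. = FALSE)
  if (ncol(features) < 1) stop("no features to train on", call. = FALSE)
  mu <- colMeans(features[tr, , drop = FALSE])
  sd_tr <- apply(features[tr, , drop = FALSE], 2, stats::sd)
  sd_tr[sd_tr == 0] <- 1  # constant feature: centered only
  std <- function(rows) sweep(sweep(features[rows, , drop = FALSE], 2, mu),
                              2, sd_tr, "/")
  model <- with_seed(seed,
    e1071::svm(std(tr), g[tr], kernel = kernel, cost = cost, scale = FALSE))
  pred <- stats::predict(model, std(va), decision.values = TRUE)
  dv <- drop(attr(pred, "decision.values"))
  # decision values are signed toward the first class named in the colname
  first <- strsplit(colnames(attr(pred, "decision.values"))[1], "/")[[1]][1]
  score <- if (first == positive) dv else -dv
  truth <- g[va]
  tp <- sum(pred == positive & truth == positive)
  tn <- sum(pred == negative & truth == negative)
  fp <- sum(pred == positive & truth == negative)
  fn <- sum(pred == negative & truth == positive)
  nv <- length(va)
  accuracy <- (tp + tn) / nv
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / nv^2
  kappa <- if (pe < 1) (accuracy - pe) / (1 - pe) else 0
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = score,
    levels = c(negative, positive), direction = "<", quiet = TRUE)))
  structure(list(accuracy = accuracy, precision = precision, recall = recall,
                 f1 = f1, kappa = kappa, roc_auc = auc,
                 n_features_selected = ncol(features),
                 split_counts = list(train = table(g[tr]),
                                     validation = table(g[va])),
                 confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
                 positive = positive, seed = seed),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(paste0("<classification_report> acc %.3f | prec %.3f | ",
                     "recall %.3f | F1 %.3f | kappa %.3f | AUC %.3f ",
                     "(%d features)\n"),
              x$accuracy, x$precision, x$recall, x$f1, x$kappa, x$roc_auc,
              x$n_features_selected))
  invisible(x)
}

#' Screen features and classify in one step
#'
#' Splits the cohort, screens features by Mann-Whitney U test (on the
#' training rows unless `paper_mode = TRUE`, which screens on all subjects
#' and therefore leaks validation information into the selection), and
#' trains/evaluates the SVM.
#'
#' @param features subjects x features matrix.
#' @param labels group labels per row.
#' @param alpha screening level (default 0.05).
#' @param train_frac training fraction (default 0.7).
#' @param seed split (and SVM) seed.
#' @param paper_mode screen on all subjects instead of training rows only.
#' @param ... passed to [train_eval_svm()].
#' @return A `classification_report`.
#' @export
classify_cohort <- function(features, labels, alpha = 0.05, train_frac = 0.7,
                            seed = 1L, paper_mode = FALSE, ...) {
  part <- split_stratified(labels, train_frac, seed)
  mask <- select_features(features, labels, alpha,
                          rows = if (paper_mode) NULL else part$train)
  if (!any(mask))
    stop("no feature passed the Mann-Whitney screen: nothing to classify",
         call. = FALSE)
  train_eval_svm(as.matrix(features)[, mask, drop = FALSE], labels, part,
                 seed = seed, ...)
}

#' Connectivity matrices for every cohort subject
#'
#' Z-scores each subject, estimates connectivity with the requested method
#' and normalizes the weights.
#'
#' @param cohort_data list with `subjects` (as from [make_cohort()] or
#'   [read_cohort()]).
#' @param method `"GCA"` or `"PCC"`.
#' @param order lag order for GCA, or `"bic"` to select per subject with
#'   [select_order_bic()].
#' @param max_order BIC search bound when `order = "bic"`.
#' @param epoch_seconds if not `NULL`, each recording is segmented into
#'   epochs of this duration, connectivity is estimated per epoch and the
#'   matrices are averaged before normalization (multi-epoch mode); `NULL`
#'   analyzes each recording as a single segment.
#' @return A list of normalized `conn_matrix` objects.
#' @export
cohort_connectivity <- function(cohort_data, method = c("GCA", "PCC"),
                                order = 5, max_order = 10,
                                epoch_seconds = NULL) {
  method <- match.arg(method)
  estimate <- function(ts) {
    if (method == "GCA") {
      p <- if (identical(order, "bic"))
        select_order_bic(ts, max_order = max_order) else order
      granger_pairwise(ts, p)
    } else {
      pearson_matrix(ts)
    }
  }
  lapply(cohort_data$subjects, function(ts) {
    W <- if (is.null(epoch_seconds)) {
      estimate(zscore(ts))
    } else {
      aggregate_epochs(lapply(segment_epochs(ts, epoch_seconds),
                              function(ep) estimate(zscore(ep))))
    }
    normalize_weights(W)
  })
}

#' Topology feature table for a list of binary networks
#'
#' @param B_list list of `binary_network` objects with identical labels.
#' @param ndc_mode passed to [feature_vector()].
#' @return A subjects x features numeric matrix with stable column names.
#' @export
cohort_features <- function(B_list, ndc_mode = "total") {
  rows <- lapply(B_list, feature_vector, ndc_mode = ndc_mode)
  do.call(rbind, rows)
}

#' Classification performance across MVAR lag orders
#'
#' Rebuilds the Granger pipeline at each candidate order — connectivity,
#' GCE threshold selection, binarization, topology features, Mann-Whitney
#' screening — and classifies with a fixed split seed, one report row per
#' order.
#'
#' @param cohort_data list with `subjects` and `manifest`.
#' @param orders candidate lag orders (default 1:10).
#' @param grid threshold grid for [select_threshold()].
#' @param alpha screening level.
#' @param train_frac training fraction.
#' @param seed split seed shared across orders.
#' @param n_repeats number of repeated stratified splits per order; the
#'   reported metrics are means across repeats (split seeds `seed`,
#'   `seed + 1`, ...). Default 1 (a single fixed split).
#' @param paper_mode passed to [classify_cohort()].
#' @param epoch_seconds passed to [cohort_connectivity()] (multi-epoch
#'   averaging mode).
#' @return A data frame with one row per order: order, selected_psw,
#'   n_features, accuracy, precision, recall, f1, kappa, roc_auc. Orders at
#'   which no feature passes the screen get `n_features = 0` and NA metrics.
#' @export
order_sweep <- function(cohort_data, orders = 1:10,
                        grid = seq(0.05, 0.5, by = 0.05), alpha = 0.05,
                        train_frac = 0.7, seed = 1L, n_repeats = 1,
                        paper_mode = FALSE, epoch_seconds = NULL) {
  labels <- cohort_data$manifest$group
  metric_cols <- c("accuracy", "precision", "recall", "f1", "kappa",
                   "roc_auc")
  do.call(rbind, lapply(orders, function(p) {
    W <- cohort_connectivity(cohort_data, "GCA", order = p,
                             epoch_seconds = epoch_seconds)
    scan <- select_threshold(W, grid)
    B <- lapply(W, proportional_binarize, psw = scan$selected_psw)
    feats <- cohort_features(B)
    reps <- lapply(seq_len(n_repeats) - 1L, function(off) {
      tryCatch(
        classify_cohort(feats, labels, alpha, train_frac, seed + off,
                        paper_mode),
        error = function(e) {
          if (!grepl("Mann-Whitney screen", conditionMessage(e))) stop(e)
          NULL  # no discriminative feature for this split
        })
    })
    reps <- Filter(Negate(is.null), reps)
    out <- data.frame(order = p, selected_psw = scan$selected_psw,
                      n_features = if (length(reps))
                        mean(vapply(reps, `[[`, numeric(1),
                                    "n_features_selected")) else 0)
    for (m in metric_cols)
      out[[m]] <- if (length(reps))
        mean(vapply(reps, `[[`, numeric(1), m)) else NA_real_
    out
  }))
}
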