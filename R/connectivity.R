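#' Weighted connectivity matrix container
#'
#' `weights[i, j]` is the influence of region i on region j (row = source,
#' column = target). Granger matrices (`method = "GCA"`) are directed and
#' nonnegative; Pearson matrices (`method = "PCC"`) are symmetric with
#' entries in [-1, 1]. The diagonal is always zero.
#'
#' @param weights n x n numeric matrix.
#' @param method `"GCA"` or `"PCC"`.
#' @param region_labels character vector of region names.
#' @param normalized logical; TRUE after [normalize_weights()].
#' @return An object of class `conn_matrix`.
#' @export
conn_matrix <- function(weights, method = c("GCA", "PCC"),
                        region_labels = NULL, normalized = FALSE) {
  method <- match.arg(method)
  weights <- as.matrix(weights)
  assert_square(weights, "weights")
  n <- nrow(weights)
  if (any(!is.finite(weights))) stop("weights must be finite", call. = FALSE)
  if (any(diag(weights) != 0)) stop("diagonal must be zero", call. = FALSE)
  if (method == "GCA" && any(weights < 0))
    stop("GCA weights must be nonnegative", call. = FALSE)
  if (method == "PCC") {
    if (max(abs(weights - t(weights))) > 1e-10)
      stop("PCC matrix must be symmetric", call. = FALSE)
    if (!normalized && any(abs(weights) > 1 + 1e-12))
      stop("PCC weights must lie in [-1, 1]", call. = FALSE)
  }
  if (is.null(region_labels)) region_labels <- paste0("R", seq_len(n))
  if (length(region_labels) != n)
    stop("label count must equal matrix dimension", call. = FALSE)
  dimnames(weights) <- NULL
  structure(list(weights = weights, directed = method == "GCA",
                 method = method, region_labels = as.character(region_labels),
                 normalized = isTRUE(normalized)),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> %s, %d regions%s%s\n", x$method,
              nrow(x$weights), if (x$directed) ", directed" else ", undirected",
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

# Lagged design helpers shared by fit_var / select_order_bic /
# granger_pairwise. Rows of the lag matrix are indexed (channel j, lag k)
# -> row (j - 1) * p + k; column t covers target time point first_t + t - 1.
lag_matrix <- function(x, p, first_t) {
  n <- nrow(x); N <- ncol(x)
  ne <- N - first_t + 1L
  M <- matrix(0, n * p, ne)
  for (j in seq_len(n)) for (k in seq_len(p))
    M[(j - 1L) * p + k, ] <- x[j, (first_t - k):(N - k)]
  M
}

#' Fit a full multivariate autoregressive model by least squares
#'
#' Regresses each channel on p lags of all channels (no intercept; signals
#' are expected to be centered, e.g. via [zscore()]). The residual
#' covariance uses the maximum-likelihood divisor `1 / n_effective` with
#' `n_effective = n_samples - order`. The reported BIC is the Gaussian
#' form `n_effective * log det(resid_cov) + k * log(n_effective)` with
#' `k = order * n_regions^2` free coefficients.
#'
#' @param ts an `roi_ts` object.
#' @param order lag order p >= 1.
#' @return An object of class `mvar_model` with elements `order`,
#'   `coeff_matrices` (row = target), `resid_cov`, `n_effective`, `bic`.
#' @export
fit_var <- function(ts, order) {
  stopifnot(inherits(ts, "roi_ts"), order >= 1)
  x <- ts$data
  n <- nrow(x); N <- ncol(x); p <- as.integer(order)
  if (N <= p * n + 1)
    stop(sprintf("need more than %d samples to fit %d channels at order %d",
                 p * n + 1, n, p), call. = FALSE)
  ne <- N - p
  Y <- t(x[, (p + 1L):N, drop = FALSE])          # ne x n
  Z <- t(lag_matrix(x, p, p + 1L))               # ne x (n*p)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    sv <- svd(Z, nu = 0, nv = 0)$d
    stop(sprintf(paste0("rank-deficient lag design (rank %d of %d, ",
                        "condition number %.3g): duplicated or collinear ",
                        "channels?"), qz$rank, ncol(Z),
                 sv[1] / max(sv[length(sv)], .Machine$double.xmin)),
         call. = FALSE)
  }
  B <- qr.coef(qz, Y)                            # (n*p) x n
  resid <- Y - Z %*% B
  sigma <- crossprod(resid) / ne
  coeff <- lapply(seq_len(p), function(k)
    t(B[(seq_len(n) - 1L) * p + k, , drop = FALSE]))
  k_free <- p * n^2
  bic <- ne * as.numeric(determinant(sigma, logarithm = TRUE)$modulus) +
    k_free * log(ne)
  structure(list(order = p, coeff_matrices = coeff, resid_cov = sigma,
                 n_effective = ne, bic = bic,
                 region_labels = ts$region_labels),
            class = "mvar_model")
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("<mvar_model> order %d, %d channels, n_eff %d, BIC %.2f\n",
              x$order, nrow(x$resid_cov), x$n_effective, x$bic))
  invisible(x)
}

#' Select the MVAR lag order by BIC
#'
#' Evaluates the BIC of full MVAR fits for each candidate order on a common
#' effective window (the last `n_samples - max_order` points), so criteria
#' are comparable across orders, and returns the argmin. Ties go to the
#' smaller order.
#'
#' @param ts an `roi_ts` object.
#' @param min_order,max_order inclusive candidate range (defaults 1 and 10).
#' @return The selected order (integer), with attribute `"bic"` holding the
#'   named vector of criteria.
#' @export
select_order_bic <- function(ts, min_order = 1, max_order = 10) {
  stopifnot(inherits(ts, "roi_ts"), min_order >= 1, max_order >= min_order)
  x <- ts$data
  n <- nrow(x); N <- ncol(x)
  pmax <- as.integer(max_order)
  ne <- N - pmax
  if (ne <= pmax * n + 1)
    stop("series too short to evaluate max_order", call. = FALSE)
  Y <- t(x[, (pmax + 1L):N, drop = FALSE])
  orders <- seq.int(min_order, max_order)
  bics <- vapply(orders, function(p) {
    Z <- t(lag_matrix(x, p, pmax + 1L))
    qz <- qr(Z)
    if (qz$rank < ncol(Z))
      stop(sprintf("rank-deficient design at order %d", p), call. = FALSE)
    resid <- Y - Z %*% qr.coef(qz, Y)
    sigma <- crossprod(resid) / ne
    ne * as.numeric(determinant(sigma, logarithm = TRUE)$modulus) +
      p * n^2 * log(ne)
  }, numeric(1))
  names(bics) <- orders
  structure(orders[which.min(bics)], bic = bics)
}

#' Pairwise Granger causality matrix
#'
#' For every ordered pair of regions (Y, X) fits two nested models of X on
#' the common effective window (the first `order` points dropped): the
#' reduced autoregression of X on its own p lags, and the full bivariate
#' regression of X on p lags of both X and Y. The causality measure is the
#' log-ratio of the maximum-likelihood residual variances,
#' \eqn{F_{Y \to X} = \ln(\sigma'^2_{X} / \sigma^2_{X})}, which is
#' nonnegative because the models are nested and both variances use the
#' same divisor.
#'
#' @param ts an `roi_ts` object (z-score first for conditioning).
#' @param order lag order p >= 1.
#' @return A directed `conn_matrix` (`method = "GCA"`) with
#'   `weights[y, x]` = F of source y onto target x.
#' @export
granger_pairwise <- function(ts, order) {
  stopifnot(inherits(ts, "roi_ts"), order >= 1)
  x <- ts$data
  n <- nrow(x); N <- ncol(x); p <- as.integer(order)
  if (N <= 2L * p + 1L)
    stop("series too short for bivariate fits at this order", call. = FALSE)
  ne <- N - p
  Y <- x[, (p + 1L):N, drop = FALSE]             # n x ne (future values)
  M <- lag_matrix(x, p, p + 1L)                  # (n*p) x ne
  G <- tcrossprod(M)                             # Gram of all lag regressors
  Cx <- tcrossprod(Y, M)                         # n x (n*p) cross-products
  S0 <- rowSums(Y^2)
  row_ix <- function(j) (j - 1L) * p + seq_len(p)
  # Reduced model: each channel on its own past only.
  sig_red <- numeric(n)
  for (i in seq_len(n)) {
    oi <- row_ix(i)
    beta <- solve(G[oi, oi, drop = FALSE], Cx[i, oi])
    sig_red[i] <- (S0[i] - sum(beta * Cx[i, oi])) / ne
  }
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {        # target
    oi <- row_ix(i)
    for (y in seq_len(n)) {      # source
      if (y == i) next
      ix <- c(oi, row_ix(y))
      beta <- solve(G[ix, ix, drop = FALSE], Cx[i, ix])
      sig_full <- (S0[i] - sum(beta * Cx[i, ix])) / ne
      if (sig_full <= 0)
        stop(sprintf(paste0("zero residual variance for region '%s': ",
                            "degenerate (deterministic) channel"),
                     ts$region_labels[i]), call. = FALSE)
      f <- log(sig_red[i] / sig_full)
      if (f < 0) {
        if (f < -1e-8)
          stop("negative causality value: numerically inconsistent fits",
               call. = FALSE)
        f <- 0  # roundoff on nested models
      }
      W[y, i] <- f
    }
  }
  conn_matrix(W, "GCA", ts$region_labels)
}

#' Pearson correlation connectivity matrix
#'
#' Symmetric matrix of Pearson correlations between all region pairs, with
#' the diagonal zeroed.
#'
#' @param ts an `roi_ts` object; no constant rows.
#' @return An undirected `conn_matrix` (`method = "PCC"`).
#' @export
pearson_matrix <- function(ts) {
  stopifnot(inherits(ts, "roi_ts"))
  sds <- apply(ts$data, 1L, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)[1]
    stop(sprintf("region '%s' (row %d) is constant",
                 ts$region_labels[bad], bad), call. = FALSE)
  }
  R <- stats::cor(t(ts$data))
  R <- (R + t(R)) / 2
  R[R > 1] <- 1; R[R < -1] <- -1
  diag(R) <- 0
  conn_matrix(R, "PCC", ts$region_labels)
}

#' Normalize connectivity weights to [0, 1]
#'
#' Pearson weights are rectified to absolute values first (thresholding
#' needs a nonnegative strength ordering); all off-diagonal weights are then
#' divided by the per-subject maximum off-diagonal magnitude, so the largest
#' entry becomes 1.
#'
#' @param W a `conn_matrix`.
#' @return A normalized `conn_matrix`.
#' @export
normalize_weights <- function(W) {
  stopifnot(inherits(W, "conn_matrix"))
  w <- W$weights
  if (W$method == "PCC") w <- abs(w)
  mx <- max(w[row(w) != col(w)])
  if (mx <= 0) stop("all-zero connectivity matrix", call. = FALSE)
  W$weights <- w / mx
  diag(W$weights) <- 0
  W$normalized <- TRUE
  W
}

#' Average connection strength of a normalized matrix
#'
#' Mean of the off-diagonal weights: all n(n-1) ordered pairs for directed
#' matrices, the n(n-1)/2 upper-triangle pairs for undirected ones.
#'
#' @param W a normalized `conn_matrix`.
#' @return A scalar in [0, 1].
#' @export
average_connection_strength <- function(W) {
  stopifnot(inherits(W, "conn_matrix"))
  w <- W$weights
  if (W$directed) mean(w[row(w) != col(w)]) else mean(w[upper.tri(w)])
}

#' Average connectivity matrices across epochs
#'
#' Elementwise mean of per-epoch connectivity matrices of the same method,
#' shape and labels (multi-epoch analysis mode).
#'
#' @param matrices list of `conn_matrix` objects.
#' @return A single `conn_matrix`.
#' @export
aggregate_epochs <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  ref <- matrices[[1]]
  for (m in matrices) {
    stopifnot(inherits(m, "conn_matrix"))
    if (m$method != ref$method || !identical(dim(m$weights), dim(ref$weights)) ||
        !identical(m$region_labels, ref$region_labels))
      stop("matrices must share method, shape and labels", call. = FALSE)
  }
  ref$weights <- Reduce(`+`, lapply(matrices, `[[`, "weights")) /
    length(matrices)
  ref$normalized <- all(vapply(matrices, `[[`, logical(1), "normalized"))
  ref
}

#' Write a connectivity matrix as TSV with a JSON sidecar
#'
#' @param W a `conn_matrix`.
#' @param path output TSV path; the sidecar is written at `<path>.json`.
#' @param extra optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_conn_matrix <- function(W, path, extra = list()) {
  stopifnot(inherits(W, "conn_matrix"))
  utils::write.table(W$weights, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- c(list(method = W$method, directed = W$directed,
                 normalized = W$normalized, region_labels = W$region_labels),
            extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
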