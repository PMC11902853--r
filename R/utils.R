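# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
assert_square <- function(m, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, " must be a square matrix", call. = FALSE)
  invisible(m)
}

# Companion-form matrix of a VAR(p): stacks the p coefficient matrices
# (row = target channel) into the (n*p) x (n*p) first-order form.
companion_matrix <- function(coeff_matrices) {
  p <- length(coeff_matrices)
  n <- nrow(coeff_matrices[[1]])
  comp <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) {
    comp[seq_len(n), (k - 1L) * n + seq_len(n)] <- coeff_matrices[[k]]
  }
  if (p > 1L) {
    comp[n + seq_len(n * (p - 1L)), seq_len(n * (p - 1L))] <-
      diag(n * (p - 1L))
  }
  comp
}

spectral_radius <- function(m) {
  max(Mod(eigen(m, only.values = TRUE)$values))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic per-subject seed derived from a cohort seed. Exact in double
# precision (inputs < 2^31 keep the product < 2^53) and bounded below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(index) * 9973) %% 2147483647)
}

# Linear indices and (row, col) pairs of the off-diagonal entries used for
# ranking: all ordered pairs for directed matrices, the upper triangle for
# undirected ones.
offdiag_pairs <- function(n, directed) {
  if (directed) {
    idx <- which(row(diag(n)) != col(diag(n)))
  } else {
    idx <- which(upper.tri(diag(n)))
  }
  cbind(row = ((idx - 1L) %% n) + 1L, col = ((idx - 1L) %/% n) + 1L)
}
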