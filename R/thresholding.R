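#' Binary network container
#'
#' Thresholded 0/1 adjacency with the row = source, column = target
#' orientation; undirected networks are stored symmetrically.
#'
#' @param adjacency n x n matrix of 0/1 entries, zero diagonal.
#' @param directed logical flag.
#' @param region_labels region names.
#' @param psw the proportional threshold that produced the network, if any.
#' @return An object of class `binary_network` with a `density` field (the
#'   retained fraction of possible off-diagonal edges).
#' @export
binary_network <- function(adjacency, directed, region_labels = NULL,
                           psw = NA_real_) {
  adjacency <- as.matrix(adjacency)
  assert_square(adjacency, "adjacency")
  if (!all(adjacency %in% c(0, 1)))
    stop("adjacency entries must be 0 or 1", call. = FALSE)
  if (any(diag(adjacency) != 0)) stop("diagonal must be zero", call. = FALSE)
  if (!directed && max(abs(adjacency - t(adjacency))) > 0)
    stop("undirected adjacency must be symmetric", call. = FALSE)
  n <- nrow(adjacency)
  if (is.null(region_labels)) region_labels <- paste0("R", seq_len(n))
  storage.mode(adjacency) <- "integer"
  m_possible <- if (directed) n * (n - 1) else n * (n - 1) / 2
  m_edges <- if (directed) sum(adjacency) else sum(adjacency) / 2
  structure(list(adjacency = adjacency, directed = directed,
                 density = m_edges / m_possible,
                 region_labels = as.character(region_labels), psw = psw),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %s, density %.3f\n",
              nrow(x$adjacency),
              if (x$directed) "directed" else "undirected", x$density))
  invisible(x)
}

# Deterministic ranking of off-diagonal weights: strength descending, then
# row ascending, then column ascending. Returns the (row, col) pairs in
# retained order.
ranked_offdiag <- function(w, directed) {
  pairs <- offdiag_pairs(nrow(w), directed)
  vals <- w[pairs]
  ord <- order(-vals, pairs[, "row"], pairs[, "col"])
  list(pairs = pairs[ord, , drop = FALSE], values = vals[ord])
}

#' Binarize a weighted matrix by proportional thresholding
#'
#' Keeps the `k = floor(psw * M)` strongest off-diagonal weights, where M is
#' the number of possible off-diagonal edges (n(n-1) directed, n(n-1)/2
#' undirected; retained undirected edges are mirrored to both triangles).
#' Ties are broken by weight descending, then row index, then column index,
#' so repeated calls give identical networks and smaller thresholds select
#' subsets of larger ones.
#'
#' @param W a normalized nonnegative `conn_matrix`.
#' @param psw proportion of strongest weights to retain, in (0, 1].
#' @return A `binary_network` at the requested density.
#' @export
proportional_binarize <- function(W, psw) {
  stopifnot(inherits(W, "conn_matrix"))
  if (any(W$weights < 0))
    stop("weights must be nonnegative; normalize_weights() first",
         call. = FALSE)
  if (psw <= 0 || psw > 1) stop("psw must be in (0, 1]", call. = FALSE)
  n <- nrow(W$weights)
  m_possible <- if (W$directed) n * (n - 1) else n * (n - 1) / 2
  k <- floor(psw * m_possible)
  if (k < 1)
    stop(sprintf("psw %.3g retains no edges for %d nodes", psw, n),
         call. = FALSE)
  rk <- ranked_offdiag(W$weights, W$directed)
  keep <- rk$pairs[seq_len(k), , drop = FALSE]
  adj <- matrix(0L, n, n)
  adj[keep] <- 1L
  if (!W$directed) adj[keep[, c("col", "row"), drop = FALSE]] <- 1L
  binary_network(adj, W$directed, W$region_labels, psw = psw)
}

#' Global cost efficiency of a thresholded network
#'
#' Binarizes at the given proportional threshold and returns the global
#' efficiency of the binary network minus the wiring cost:
#' GCE = E - PSW.
#'
#' @param W a normalized nonnegative `conn_matrix`.
#' @param psw proportional threshold in (0, 1].
#' @return A scalar; attribute `"efficiency"` holds E itself.
#' @export
global_cost_efficiency <- function(W, psw) {
  B <- proportional_binarize(W, psw)
  e <- binary_global_efficiency(B$adjacency, B$directed)
  structure(e - psw, efficiency = e)
}

#' Select a group-level proportional threshold by GCE maximization
#'
#' Evaluates the mean global cost efficiency across subjects at each grid
#' threshold and selects the argmax; ties go to the smaller threshold. The
#' single selected threshold is intended to be applied to every subject of
#' the method. Grid points that would retain no edges are skipped with a
#' recorded warning.
#'
#' @param W_list list of normalized `conn_matrix` objects with uniform
#'   directedness.
#' @param grid ascending threshold grid (default 0.05 to 0.50 step 0.05).
#' @return An object of class `threshold_scan`: a data frame `scan`
#'   (psw, mean_E, mean_GCE), `selected_psw`, and `skipped` grid points.
#' @export
select_threshold <- function(W_list, grid = seq(0.05, 0.5, by = 0.05)) {
  stopifnot(length(W_list) >= 1, all(diff(grid) > 0))
  dirs <- vapply(W_list, `[[`, logical(1), "directed")
  if (length(unique(dirs)) != 1)
    stop("subjects mix directed and undirected matrices", call. = FALSE)
  skipped <- numeric(0)
  rows <- lapply(grid, function(psw) {
    res <- tryCatch(
      vapply(W_list, function(W) {
        g <- global_cost_efficiency(W, psw)
        c(attr(g, "efficiency"), as.numeric(g))
      }, numeric(2)),
      error = function(e) NULL)
    if (is.null(res)) {
      skipped <<- c(skipped, psw)
      warning(sprintf("grid point %.3g infeasible, skipped", psw),
              call. = FALSE)
      return(NULL)
    }
    data.frame(psw = psw, mean_E = mean(res[1, ]), mean_GCE = mean(res[2, ]))
  })
  scan <- do.call(rbind, rows)
  if (is.null(scan) || nrow(scan) == 0)
    stop("no feasible grid point", call. = FALSE)
  sel <- scan$psw[which.max(scan$mean_GCE)]  # first max: smaller psw on ties
  structure(list(scan = scan, selected_psw = sel, skipped = skipped),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("<threshold_scan> %d grid points, selected PSW = %.2f\n",
              nrow(x$scan), x$selected_psw))
  print(x$scan, row.names = FALSE)
  invisible(x)
}

#' Write a threshold scan as CSV
#' @param scan a `threshold_scan`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_threshold_scan <- function(scan, path) {
  utils::write.csv(scan$scan, path, row.names = FALSE)
  invisible(path)
}
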