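# Graph-theoretic features of binary brain networks: four global measures
# (clustering, characteristic path length, global and local efficiency) and
# four nodal measures (clustering, efficiency, local efficiency, degree
# centrality), on directed or undirected 0/1 adjacency matrices.

as_igraph <- function(adj, directed) {
  igraph::graph_from_adjacency_matrix(adj,
    mode = if (directed) "directed" else "undirected")
}

# Mean inverse shortest-path length over ordered pairs; 0 for n < 2.
# Unreachable pairs contribute 0 (1/Inf).
binary_global_efficiency <- function(adj, directed) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- igraph::distances(as_igraph(adj, directed), mode = "out")
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Shortest-path length matrix of a binary network
#'
#' Unweighted shortest-path (hop-count) distances between all node pairs,
#' following edge direction for directed networks. Unreachable pairs are
#' `Inf`; the diagonal is 0.
#'
#' @param B a `binary_network`.
#' @return An n x n numeric matrix.
#' @export
shortest_path_lengths <- function(B) {
  stopifnot(inherits(B, "binary_network"))
  d <- igraph::distances(as_igraph(B$adjacency, B$directed), mode = "out")
  dimnames(d) <- list(B$region_labels, B$region_labels)
  d
}

# Fagiolo's directed clustering coefficient: all directed triangle motifs
# through a node over the corrected number of possible ones,
#   C_i = [(A + A')^3]_ii / (2 [d_tot(d_tot - 1) - 2 d_bi]),
# with d_tot the total (in + out) degree and d_bi the reciprocal degree.
directed_clustering <- function(adj) {
  A <- adj * 1.0
  S <- A + t(A)
  num <- diag(S %*% S %*% S)
  dtot <- rowSums(A) + colSums(A)
  dbi <- diag(A %*% A)
  den <- 2 * (dtot * (dtot - 1) - 2 * dbi)
  ifelse(den > 0, num / den, 0)
}

undirected_clustering <- function(adj) {
  A <- adj * 1.0
  num <- diag(A %*% A %*% A)
  deg <- rowSums(A)
  den <- deg * (deg - 1)
  ifelse(den > 0, num / den, 0)
}

#' Nodal graph metrics
#'
#' Per-region measures on a binary network:
#' * `ncc` — clustering coefficient (Fagiolo's directed form with
#'   reciprocal-degree correction, or the standard undirected form);
#' * `ne` — nodal efficiency, the mean inverse distance from the node to
#'   every other node (unreachable = 0);
#' * `nle` — local efficiency, the global efficiency of the subgraph
#'   induced by the node's neighbors (union of in- and out-neighbors);
#'   0 with fewer than 2 neighbors;
#' * `ndc` — degree centrality: in-degree + out-degree for directed
#'   networks (or out-degree only with `ndc_mode = "out"`), plain degree
#'   for undirected ones.
#'
#' @param B a `binary_network` with at least 2 nodes.
#' @param ndc_mode `"total"` (default) or `"out"` degree for directed
#'   networks.
#' @return A data frame with columns region, ncc, ne, nle, ndc.
#' @export
nodal_metrics <- function(B, ndc_mode = c("total", "out")) {
  stopifnot(inherits(B, "binary_network"))
  ndc_mode <- match.arg(ndc_mode)
  adj <- B$adjacency
  n <- nrow(adj)
  if (n < 2) stop("network must have at least 2 nodes", call. = FALSE)
  d <- igraph::distances(as_igraph(adj, B$directed), mode = "out")
  inv <- 1 / d
  diag(inv) <- 0
  ne <- rowSums(inv) / (n - 1)
  ncc <- if (B$directed) directed_clustering(adj) else
    undirected_clustering(adj)
  nle <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] | adj[, i])
    nb <- setdiff(nb, i)
    if (length(nb) < 2) return(0)
    binary_global_efficiency(adj[nb, nb, drop = FALSE], B$directed)
  }, numeric(1))
  ndc <- if (B$directed) {
    if (ndc_mode == "total") rowSums(adj) + colSums(adj) else rowSums(adj)
  } else rowSums(adj)
  data.frame(region = B$region_labels, ncc = ncc, ne = ne, nle = nle,
             ndc = as.numeric(ndc), stringsAsFactors = FALSE)
}

#' Global graph metrics
#'
#' Four whole-network measures of a binary network:
#' * `gcc` — global clustering coefficient, the mean nodal clustering;
#' * `gclp` — characteristic path length, the mean shortest-path length
#'   over reachable ordered pairs (an error if no pair is reachable);
#' * `ge` — global efficiency, the mean inverse distance over all ordered
#'   pairs (unreachable pairs contribute 0);
#' * `gle` — global local efficiency, the mean nodal local efficiency.
#'
#' @param B a `binary_network`.
#' @param ndc_mode passed to [nodal_metrics()].
#' @return A named list with `gcc`, `gclp`, `ge`, `gle`.
#' @export
global_metrics <- function(B, ndc_mode = "total") {
  nod <- nodal_metrics(B, ndc_mode)
  d <- igraph::distances(as_igraph(B$adjacency, B$directed), mode = "out")
  off <- row(d) != col(d)
  finite <- off & is.finite(d)
  if (!any(finite))
    stop("no reachable node pair: characteristic path length undefined",
         call. = FALSE)
  inv <- 1 / d
  diag(inv) <- 0
  list(gcc = mean(nod$ncc), gclp = mean(d[finite]),
       ge = sum(inv) / sum(off), gle = mean(nod$nle))
}

#' Flattened topology feature vector
#'
#' Deterministic ordering used for classification: the four global metrics
#' `[GCC, GCLP, GE, GLE]` followed by one `[NCC, NE, NLE, NDC]` block per
#' region in label order — `4 + 4n` features (468 for 116 regions).
#'
#' @param B a `binary_network`.
#' @param ndc_mode passed to [nodal_metrics()].
#' @return A named numeric vector of length `4 + 4 * n_regions`.
#' @export
feature_vector <- function(B, ndc_mode = "total") {
  g <- global_metrics(B, ndc_mode)
  nod <- nodal_metrics(B, ndc_mode)
  nodal <- as.vector(t(as.matrix(nod[, c("ncc", "ne", "nle", "ndc")])))
  names(nodal) <- as.vector(vapply(nod$region, function(r)
    paste0(c("NCC_", "NE_", "NLE_", "NDC_"), r), character(4)))
  c(GCC = g$gcc, GCLP = g$gclp, GE = g$ge, GLE = g$gle, nodal)
}
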