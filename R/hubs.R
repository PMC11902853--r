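# Hub identification from weighted group-level connectivity: the strongest
# connections, the most group-dissimilar connections, the highest
# out-strength regions, the most group-dissimilar out-strength regions, and
# a consensus frequency count across the four rankings.

check_same_shape <- function(a, b) {
  stopifnot(inherits(a, "conn_matrix"), inherits(b, "conn_matrix"))
  if (!identical(dim(a$weights), dim(b$weights)) ||
      !identical(a$region_labels, b$region_labels))
    stop("matrices must share shape and region labels", call. = FALSE)
}

#' Group-mean connectivity matrix
#'
#' Elementwise mean of per-subject normalized matrices of one group.
#'
#' @param W_list list of `conn_matrix` objects with identical shape, method
#'   and labels.
#' @return A `conn_matrix`.
#' @export
group_mean_matrix <- function(W_list) {
  stopifnot(length(W_list) >= 1)
  for (m in W_list[-1]) check_same_shape(W_list[[1]], m)
  out <- W_list[[1]]
  out$weights <- Reduce(`+`, lapply(W_list, `[[`, "weights")) / length(W_list)
  out
}

#' Strongest connections of a group matrix
#'
#' The k off-diagonal entries with the highest strength, sorted descending;
#' ties broken by row then column index.
#'
#' @param W_mean a `conn_matrix` (typically a group mean).
#' @param k number of connections (default 20); truncated with a warning if
#'   it exceeds the number of off-diagonal entries.
#' @return A data frame: source, target, strength.
#' @export
top_connections <- function(W_mean, k = 20) {
  stopifnot(inherits(W_mean, "conn_matrix"), k >= 1)
  rk <- ranked_offdiag(W_mean$weights, W_mean$directed)
  m <- nrow(rk$pairs)
  if (k > m) {
    warning(sprintf("k = %d exceeds the %d available connections", k, m),
            call. = FALSE)
    k <- m
  }
  sel <- seq_len(k)
  data.frame(source = W_mean$region_labels[rk$pairs[sel, "row"]],
             target = W_mean$region_labels[rk$pairs[sel, "col"]],
             strength = rk$values[sel], stringsAsFactors = FALSE)
}

#' Most dissimilar connections between two group matrices
#'
#' Ranks off-diagonal entries by the absolute patient-minus-control
#' difference; the signed difference is kept so each connection can be
#' labelled increased or decreased.
#'
#' @param W_patient_mean,W_control_mean group-mean `conn_matrix` objects of
#'   identical shape.
#' @param k number of connections (default 20).
#' @return A data frame: source, target, delta, abs_delta.
#' @export
dissimilar_connections <- function(W_patient_mean, W_control_mean, k = 20) {
  check_same_shape(W_patient_mean, W_control_mean)
  stopifnot(k >= 1)
  D <- W_patient_mean$weights - W_control_mean$weights
  pairs <- offdiag_pairs(nrow(D), W_patient_mean$directed)
  vals <- D[pairs]
  ord <- order(-abs(vals), pairs[, "row"], pairs[, "col"])
  k <- min(k, length(ord))
  sel <- ord[seq_len(k)]
  data.frame(source = W_patient_mean$region_labels[pairs[sel, "row"]],
             target = W_patient_mean$region_labels[pairs[sel, "col"]],
             delta = vals[sel], abs_delta = abs(vals[sel]),
             stringsAsFactors = FALSE)
}

#' Regions with the highest out-strength
#'
#' Ranks regions by out-strength — the row sum of the directed weighted
#' matrix, i.e. the summed strength of a region's outgoing connections.
#' Ties go to label (row) order.
#'
#' @param W_mean a directed `conn_matrix`.
#' @param k number of regions (default 5).
#' @return A data frame: region, out_strength.
#' @export
out_strength_ranking <- function(W_mean, k = 5) {
  stopifnot(inherits(W_mean, "conn_matrix"), k >= 1)
  if (!W_mean$directed)
    stop("out-strength requires a directed matrix", call. = FALSE)
  s <- rowSums(W_mean$weights)
  ord <- order(-s, seq_along(s))
  k <- min(k, length(s))
  sel <- ord[seq_len(k)]
  data.frame(region = W_mean$region_labels[sel], out_strength = s[sel],
             stringsAsFactors = FALSE)
}

#' Regions with the most dissimilar out-strength between groups
#'
#' Ranks regions by the absolute patient-minus-control out-strength
#' difference, keeping the sign.
#'
#' @param W_patient_mean,W_control_mean directed group-mean matrices of
#'   identical shape.
#' @param k number of regions (default 5).
#' @return A data frame: region, delta, abs_delta.
#' @export
out_strength_dissimilarity <- function(W_patient_mean, W_control_mean,
                                       k = 5) {
  check_same_shape(W_patient_mean, W_control_mean)
  if (!W_patient_mean$directed)
    stop("out-strength requires directed matrices", call. = FALSE)
  stopifnot(k >= 1)
  d <- rowSums(W_patient_mean$weights) - rowSums(W_control_mean$weights)
  ord <- order(-abs(d), seq_along(d))
  k <- min(k, length(d))
  sel <- ord[seq_len(k)]
  data.frame(region = W_patient_mean$region_labels[sel], delta = d[sel],
             abs_delta = abs(d[sel]), stringsAsFactors = FALSE)
}

#' Consensus hub determination across the four rankings
#'
#' Counts, for every region, in how many of the four ranking lists it
#' appears (edge lists contribute both endpoints, counted at most once per
#' list). Regions appearing in at least `min_lists` lists are reported as
#' hubs.
#'
#' @param lcs data frame from [top_connections()].
#' @param gdc data frame from [dissimilar_connections()].
#' @param hodr data frame from [out_strength_ranking()].
#' @param gdr data frame from [out_strength_dissimilarity()].
#' @param min_lists minimum appearance frequency for hub status (default 2).
#' @return An object of class `hub_report`: `frequency` (data frame region,
#'   frequency, sorted by decreasing frequency), `hubs` (character vector),
#'   the four input lists and `min_lists`.
#' @export
hub_consensus <- function(lcs, gdc, hodr, gdr, min_lists = 2) {
  sets <- list(lcs = unique(c(lcs$source, lcs$target)),
               gdc = unique(c(gdc$source, gdc$target)),
               hodr = unique(hodr$region),
               gdr = unique(gdr$region))
  regions <- unique(unlist(sets))
  freq <- vapply(regions, function(r)
    sum(vapply(sets, function(s) r %in% s, logical(1))), integer(1))
  ord <- order(-freq, regions)
  frequency <- data.frame(region = regions[ord], frequency = freq[ord],
                          stringsAsFactors = FALSE)
  structure(list(frequency = frequency,
                 hubs = frequency$region[frequency$frequency >= min_lists],
                 lists = list(lcs = lcs, gdc = gdc, hodr = hodr, gdr = gdr),
                 min_lists = min_lists),
            class = "hub_report")
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf("<hub_report> %d hubs (frequency >= %d of 4 lists)\n",
              length(x$hubs), x$min_lists))
  print(utils::head(x$frequency, 15), row.names = FALSE)
  invisible(x)
}

#' Write a hub report as JSON plus flat CSV tables
#'
#' @param report a `hub_report`.
#' @param dir output directory (created if missing).
#' @param prefix filename prefix (default `"hubs"`).
#' @return The JSON path, invisibly.
#' @export
write_hub_report <- function(report, dir, prefix = "hubs") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(list(hubs = report$hubs,
                            min_lists = report$min_lists,
                            frequency = report$frequency,
                            lists = report$lists),
                       json_path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$frequency,
                   file.path(dir, paste0(prefix, "_frequency.csv")),
                   row.names = FALSE)
  for (nm in names(report$lists))
    utils::write.csv(report$lists[[nm]],
                     file.path(dir, paste0(prefix, "_", nm, ".csv")),
                     row.names = FALSE)
  invisible(json_path)
}
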