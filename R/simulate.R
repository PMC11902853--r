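#' Specification of a stationary MVAR process
#'
#' Defines the generating model for synthetic ROI signals: a multivariate
#' autoregressive process \eqn{x_t = \sum_{k=1}^p A_k x_{t-k} + \epsilon_t}
#' with Gaussian innovations. Coefficient matrices follow the row = target
#' convention: `coeff_matrices[[k]][i, j]` is the gain from channel j's past
#' (lag k) onto channel i.
#'
#' @param n_regions number of channels.
#' @param order lag order p.
#' @param coeff_matrices list of p `n_regions x n_regions` coefficient
#'   matrices; the companion matrix must have spectral radius < 1.
#' @param noise_cov symmetric positive-definite innovation covariance
#'   (default identity).
#' @param n_samples samples to return after burn-in (default 1000).
#' @param burn_in initialization samples discarded before returning
#'   (default 500).
#' @param seed integer RNG seed.
#' @param sampling_rate_hz nominal sampling rate attached to the output
#'   (default 500).
#' @return An object of class `mvar_spec`.
#' @export
simulation_spec <- function(n_regions, order, coeff_matrices,
                            noise_cov = diag(n_regions), n_samples = 1000,
                            burn_in = 500, seed = 1L,
                            sampling_rate_hz = 500) {
  stopifnot(n_regions >= 1, order >= 1)
  if (!is.list(coeff_matrices) || length(coeff_matrices) != order)
    stop("coeff_matrices must be a list of `order` matrices", call. = FALSE)
  for (A in coeff_matrices) {
    assert_square(A, "coefficient matrix")
    if (nrow(A) != n_regions)
      stop("coefficient matrices must be n_regions x n_regions",
           call. = FALSE)
  }
  rho <- spectral_radius(companion_matrix(coeff_matrices))
  if (rho >= 1)
    stop(sprintf(paste0("non-stationary coefficient set: companion spectral ",
                        "radius %.4f >= 1"), rho), call. = FALSE)
  noise_cov <- as.matrix(noise_cov)
  assert_square(noise_cov, "noise_cov")
  if (max(abs(noise_cov - t(noise_cov))) > 1e-10)
    stop("noise_cov must be symmetric", call. = FALSE)
  chol_ok <- tryCatch({chol(noise_cov); TRUE}, error = function(e) FALSE)
  if (!chol_ok)
    stop("noise_cov must be positive definite", call. = FALSE)
  if (n_samples < order + 1)
    stop("n_samples must be at least order + 1", call. = FALSE)
  structure(list(n_regions = as.integer(n_regions), order = as.integer(order),
                 coeff_matrices = coeff_matrices, noise_cov = noise_cov,
                 n_samples = as.integer(n_samples),
                 burn_in = as.integer(burn_in), seed = as.integer(seed),
                 sampling_rate_hz = sampling_rate_hz,
                 spectral_radius = rho),
            class = "mvar_spec")
}

#' Simulate one subject from an MVAR specification
#'
#' Runs the VAR recursion from a zero initial state, discards the burn-in
#' segment, and returns the remaining `n_samples` points. Deterministic for
#' a given spec and seed.
#'
#' @param spec an `mvar_spec` from [simulation_spec()].
#' @param subject_id,group metadata attached to the output.
#' @param seed optional seed overriding `spec$seed`.
#' @return An `roi_ts` object, `n_regions x n_samples`.
#' @export
simulate_mvar <- function(spec, subject_id = "sim", group = "", seed = NULL) {
  stopifnot(inherits(spec, "mvar_spec"))
  n <- spec$n_regions
  p <- spec$order
  total <- spec$burn_in + spec$n_samples + p
  L <- t(chol(spec$noise_cov))
  innov <- with_seed(seed %||% spec$seed,
                     L %*% matrix(stats::rnorm(n * total), n, total))
  x <- matrix(0, n, total)
  A <- spec$coeff_matrices
  for (t in (p + 1L):total) {
    acc <- innov[, t]
    for (k in seq_len(p)) acc <- acc + A[[k]] %*% x[, t - k]
    x[, t] <- acc
  }
  out <- x[, (total - spec$n_samples + 1L):total, drop = FALSE]
  roi_timeseries(out, sampling_rate_hz = spec$sampling_rate_hz,
                 subject_id = subject_id, group = group)
}

#' Random sparse stable MVAR specification
#'
#' Convenience generator used for synthetic cohorts: each channel keeps a
#' lag-1 self-coefficient and `n_edges` directed cross-couplings are planted
#' at random lags with gain `cross_gain`. If the resulting companion matrix
#' has spectral radius >= 0.95 all coefficients are shrunk until it drops
#' below 0.95, keeping the process comfortably stationary.
#'
#' @param n_regions number of channels (default 20).
#' @param order lag order (default 2).
#' @param n_edges number of planted directed cross-couplings (default
#'   `n_regions`).
#' @param self_coef lag-1 diagonal coefficient (default 0.3).
#' @param cross_gain magnitude of planted cross-couplings (default 0.3).
#' @param seed integer seed controlling edge placement.
#' @param ... passed through to [simulation_spec()].
#' @return An `mvar_spec`; the planted edges are stored in attribute
#'   `"planted_edges"` as a (source, target, lag) matrix.
#' @export
random_mvar_spec <- function(n_regions = 20, order = 2, n_edges = n_regions,
                             self_coef = 0.3, cross_gain = 0.3, seed = 1L,
                             ...) {
  stopifnot(n_edges <= n_regions * (n_regions - 1))
  edges <- with_seed(seed, {
    pairs <- offdiag_pairs(n_regions, directed = TRUE)
    pick <- sample(nrow(pairs), n_edges)
    cbind(source = pairs[pick, "row"], target = pairs[pick, "col"],
          lag = sample(order, n_edges, replace = TRUE))
  })
  A <- replicate(order, matrix(0, n_regions, n_regions), simplify = FALSE)
  diag(A[[1]]) <- self_coef
  for (e in seq_len(n_edges))
    A[[edges[e, "lag"]]][edges[e, "target"], edges[e, "source"]] <- cross_gain
  while (spectral_radius(companion_matrix(A)) >= 0.95)
    A <- lapply(A, function(m) 0.9 * m)
  spec <- simulation_spec(n_regions, order, A, seed = seed, ...)
  attr(spec, "planted_edges") <- edges
  spec
}

#' Fixed five-channel MVAR(5) demonstration process
#'
#' A deterministic 5-channel, order-5 process used to exercise lag-order
#' selection: weak lag-1 self-memory plus strong ring couplings at lag 5,
#' so that a fitted model must reach back five lags to capture the dynamics.
#'
#' @param n_samples samples per realization (default 1000).
#' @param seed RNG seed.
#' @return An `mvar_spec` with `order = 5`.
#' @export
mvar5_demo_spec <- function(n_samples = 1000, seed = 1L) {
  n <- 5L
  A <- replicate(5, matrix(0, n, n), simplify = FALSE)
  diag(A[[1]]) <- 0.25
  for (i in seq_len(n)) A[[5]][i, (i %% n) + 1L] <- 0.45
  diag(A[[5]]) <- -0.35
  simulation_spec(n, 5L, A, n_samples = n_samples, seed = seed)
}

#' Canonical two-group validation cohort
#'
#' The package's reference synthetic cohort: a 20-region order-5 base
#' process in which every channel keeps lag-1 self-memory, regions 1-8
#' carry two feed-forward coupling chains at lags 1-3, and the patient
#' group receives an additive coupling increase on five feed-forward edges
#' from three hub sources (regions 1-3) onto five distinct sink regions
#' (11-15) at lag 5. The effect graph is acyclic and the sinks are
#' otherwise uncoupled, so each (source, sink) pair is exactly a bivariate
#' VAR(5) and the group difference is invisible to models of order below
#' four. Group sizes default to 14 controls vs 34 patients.
#'
#' @param seed cohort seed.
#' @param n_group_a,n_group_b group sizes (defaults 14 and 34).
#' @param effect_gain coupling increment on the five effect edges
#'   (default 0.3; 0 gives an exchangeable null cohort).
#' @param n_samples samples per subject (default 1000, i.e. one 2 s epoch
#'   at 500 Hz).
#' @return A `cohort_spec`.
#' @export
demo_cohort_spec <- function(seed = 1L, n_group_a = 14, n_group_b = 34,
                             effect_gain = 0.3, n_samples = 1000) {
  n <- 20L
  A <- replicate(5, matrix(0, n, n), simplify = FALSE)
  diag(A[[1]]) <- 0.3
  A[[1]][2, 1] <- 0.3; A[[2]][3, 2] <- 0.3; A[[3]][4, 3] <- 0.3
  A[[1]][6, 5] <- 0.3; A[[2]][7, 6] <- 0.3; A[[3]][8, 7] <- 0.3
  base <- simulation_spec(n, 5L, A, n_samples = n_samples, seed = seed)
  cohort_spec(n_group_a, n_group_b, base,
              effect_edges = cbind(c(1, 1, 2, 2, 3), c(11, 12, 13, 14, 15)),
              effect_gain = effect_gain, effect_lag = 5L, seed = seed)
}

#' Cohort specification with a planted group effect
#'
#' Describes a two-group synthetic cohort: group A subjects are drawn from
#' `base_spec`; group B subjects from the same process with `effect_gain`
#' added to the coupling coefficient of each `(source, target)` pair in
#' `effect_edges` at lag `effect_lag`. The default lag is the base order, so
#' a fitted model must use at least that many lags to see the group effect.
#'
#' @param n_group_a,n_group_b subject counts (defaults 14 and 34).
#' @param base_spec an `mvar_spec` shared by both groups.
#' @param effect_edges integer matrix (or 2-column data frame) of
#'   (source, target) node pairs receiving the effect; may have zero rows.
#' @param effect_gain additive coupling increment, >= 0 (default 0.3).
#' @param effect_lag lag at which the increment is applied (default
#'   `base_spec$order`).
#' @param seed cohort seed; per-subject seeds are derived from it.
#' @param group_labels length-2 character vector (default `c("HC","TLE")`).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_group_a = 14, n_group_b = 34, base_spec,
                        effect_edges = NULL, effect_gain = 0.3,
                        effect_lag = base_spec$order, seed = 1L,
                        group_labels = c("HC", "TLE")) {
  stopifnot(inherits(base_spec, "mvar_spec"),
            n_group_a >= 1, n_group_b >= 1, effect_gain >= 0,
            effect_lag >= 1, effect_lag <= base_spec$order,
            length(group_labels) == 2)
  if (is.null(effect_edges)) {
    effect_edges <- matrix(integer(0), 0, 2)
  } else {
    effect_edges <- as.matrix(effect_edges)
    storage.mode(effect_edges) <- "integer"
  }
  if (nrow(effect_edges)) {
    if (ncol(effect_edges) != 2)
      stop("effect_edges must have two columns (source, target)",
           call. = FALSE)
    if (any(effect_edges < 1) || any(effect_edges > base_spec$n_regions))
      stop("effect_edges reference node indices outside 1..n_regions",
           call. = FALSE)
    if (any(effect_edges[, 1] == effect_edges[, 2]))
      stop("effect_edges must not be self-loops", call. = FALSE)
  }
  colnames(effect_edges) <- c("source", "target")
  structure(list(n_group_a = as.integer(n_group_a),
                 n_group_b = as.integer(n_group_b),
                 base_spec = base_spec, effect_edges = effect_edges,
                 effect_gain = effect_gain,
                 effect_lag = as.integer(effect_lag),
                 seed = as.integer(seed), group_labels = group_labels),
            class = "cohort_spec")
}

# Coefficient matrices of the effect (group B) process.
effect_coeffs <- function(cohort) {
  A <- cohort$base_spec$coeff_matrices
  ee <- cohort$effect_edges
  for (e in seq_len(nrow(ee)))
    A[[cohort$effect_lag]][ee[e, "target"], ee[e, "source"]] <-
      A[[cohort$effect_lag]][ee[e, "target"], ee[e, "source"]] +
      cohort$effect_gain
  A
}

#' Simulate a labelled two-group cohort
#'
#' Group A subjects use the base process; group B subjects use the
#' effect-augmented process. Each subject gets a seed derived
#' deterministically from the cohort seed and the subject index, so the
#' cohort is reproducible while subjects remain independent.
#'
#' @param cohort a `cohort_spec`.
#' @return A list with `subjects` (list of `roi_ts`) and `manifest`
#'   (data frame: subject_id, group, seed).
#' @export
make_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  base <- cohort$base_spec
  A_eff <- effect_coeffs(cohort)
  rho <- spectral_radius(companion_matrix(A_eff))
  if (rho >= 1)
    stop(sprintf(paste0("effect_gain %.3g makes the group-%s process ",
                        "non-stationary (companion spectral radius %.4f)"),
                 cohort$effect_gain, cohort$group_labels[2], rho),
         call. = FALSE)
  spec_eff <- simulation_spec(base$n_regions, base$order, A_eff,
                              base$noise_cov, base$n_samples, base$burn_in,
                              base$seed, base$sampling_rate_hz)
  n_total <- cohort$n_group_a + cohort$n_group_b
  groups <- rep(cohort$group_labels, c(cohort$n_group_a, cohort$n_group_b))
  subjects <- vector("list", n_total)
  seeds <- integer(n_total)
  for (i in seq_len(n_total)) {
    seeds[i] <- derive_seed(cohort$seed, i)
    sid <- sprintf("S%03d", i)
    sp <- if (groups[i] == cohort$group_labels[1]) base else spec_eff
    subjects[[i]] <- simulate_mvar(sp, subject_id = sid, group = groups[i],
                                   seed = seeds[i])
  }
  list(subjects = subjects,
       manifest = data.frame(subject_id = sprintf("S%03d", seq_len(n_total)),
                             group = groups, seed = seeds,
                             stringsAsFactors = FALSE))
}

#' Ground-truth directed graph of an MVAR specification
#'
#' Edge source -> target exists iff any lag's coefficient from the source
#' channel onto the target channel is nonzero (off-diagonal only). The
#' adjacency follows the row = source, column = target orientation used by
#' connectivity matrices.
#'
#' @param spec an `mvar_spec`.
#' @return A directed `binary_network`.
#' @export
ground_truth_graph <- function(spec) {
  stopifnot(inherits(spec, "mvar_spec"))
  n <- spec$n_regions
  adj <- matrix(0L, n, n)
  for (A in spec$coeff_matrices) adj <- adj | (t(A) != 0)  # A is row=target
  adj <- adj * 1L
  diag(adj) <- 0L
  binary_network(adj, directed = TRUE,
                 region_labels = paste0("R", seq_len(n)))
}

#' Write a simulated cohort to disk
#'
#' Emits one TSV matrix per subject, a manifest CSV (subject_id, group,
#' path, seed) and, when the generating spec is supplied, a JSON
#' ground-truth edge list.
#'
#' @param cohort_data result of [make_cohort()].
#' @param dir output directory, created if missing.
#' @param spec optional `mvar_spec` whose ground-truth graph is written as
#'   `ground_truth.json`.
#' @return The manifest data frame (with a `path` column), invisibly.
#' @export
write_cohort <- function(cohort_data, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort_data$manifest
  man$path <- file.path(dir, paste0(man$subject_id, ".tsv"))
  for (i in seq_along(cohort_data$subjects))
    write_roi_timeseries(cohort_data$subjects[[i]], man$path[i])
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(spec)) {
    gt <- ground_truth_graph(spec)
    edges <- which(gt$adjacency == 1L, arr.ind = TRUE)
    jsonlite::write_json(
      list(n_regions = spec$n_regions,
           edges = data.frame(source = edges[, 1], target = edges[, 2])),
      file.path(dir, "ground_truth.json"))
  }
  invisible(man)
}

#' Read a cohort from a manifest CSV
#'
#' @param manifest_path CSV with columns subject_id, group, path (paths
#'   relative to the manifest's directory or absolute).
#' @param sampling_rate_hz sampling rate to attach.
#' @return A list with `subjects` and `manifest`, as [make_cohort()].
#' @export
read_cohort <- function(manifest_path, sampling_rate_hz = 500) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  paths <- ifelse(file.exists(man$path), man$path,
                  file.path(dirname(manifest_path), man$path))
  subjects <- lapply(seq_len(nrow(man)), function(i)
    read_roi_timeseries(paths[i], sampling_rate_hz = sampling_rate_hz,
                        subject_id = man$subject_id[i], group = man$group[i]))
  list(subjects = subjects, manifest = man)
}
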