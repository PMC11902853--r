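# End-to-end orchestration: cohort -> connectivity -> threshold ->
# binary networks -> topology features -> group tests -> hub report ->
# classification, with a reproducible run manifest.

#' Build a validated pipeline configuration
#'
#' Either `manifest_path` (a cohort on disk) or `cohort` (a `cohort_spec`
#' to simulate) must be given. All stage parameters have the defaults used
#' throughout the package.
#'
#' @param manifest_path optional cohort manifest CSV (subject_id, group,
#'   path).
#' @param cohort optional `cohort_spec` to simulate instead.
#' @param methods connectivity methods to run, subset of `c("GCA","PCC")`.
#' @param order GCA lag order, or `"bic"` for per-subject BIC selection.
#' @param grid proportional-threshold grid in (0, 1].
#' @param alpha Mann-Whitney screening level.
#' @param train_frac training fraction in (0, 1).
#' @param seed split/classifier seed.
#' @param paper_mode screen features on all subjects (whole-sample
#'   protocol, with a leakage caveat) instead of training rows only.
#' @param ndc_mode degree-centrality convention, `"total"` or `"out"`.
#' @param hub_k_edges,hub_k_regions ranking lengths (defaults 20 and 5).
#' @param out_dir output directory.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest_path = NULL, cohort = NULL,
                            methods = c("GCA", "PCC"), order = 5,
                            grid = seq(0.05, 0.5, by = 0.05), alpha = 0.05,
                            train_frac = 0.7, seed = 1L, paper_mode = FALSE,
                            ndc_mode = "total", hub_k_edges = 20,
                            hub_k_regions = 5, out_dir = tempfile("gcnet_")) {
  if (is.null(manifest_path) && is.null(cohort))
    stop("supply manifest_path or cohort", call. = FALSE)
  if (!is.null(manifest_path) && !file.exists(manifest_path))
    stop("manifest not found: ", manifest_path, call. = FALSE)
  if (!is.null(cohort)) stopifnot(inherits(cohort, "cohort_spec"))
  methods <- match.arg(methods, c("GCA", "PCC"), several.ok = TRUE)
  stopifnot(all(grid > 0), all(grid <= 1), train_frac > 0, train_frac < 1)
  structure(list(manifest_path = manifest_path, cohort = cohort,
                 methods = methods, order = order, grid = grid,
                 alpha = alpha, train_frac = train_frac,
                 seed = as.integer(seed), paper_mode = paper_mode,
                 ndc_mode = ndc_mode, hub_k_edges = hub_k_edges,
                 hub_k_regions = hub_k_regions, out_dir = out_dir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config[setdiff(names(config), "out_dir")], tmp)
  unname(tools::md5sum(tmp))
}

stage_log <- function(stage, detail, t0) {
  message(sprintf("[gcnet] %-12s %-28s %6.2fs", stage, detail,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full analysis pipeline
#'
#' Executes every stage for each configured method and writes the complete
#' bundle under `config$out_dir`: per-subject normalized connectivity
#' matrices (TSV + JSON sidecars), the threshold scan (CSV), binary
#' networks (TSV), the topology feature table (CSV), per-feature group
#' tests (CSV), the hub report (JSON + CSVs), the classification report
#' (JSON) and a run manifest with the config hash and seeds. Identical
#' config and seeds yield an identical bundle.
#'
#' @param config a `pipeline_config`.
#' @return The report bundle (named list, one entry per method plus
#'   `manifest`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- as.numeric(Sys.time())
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fail <- function(stage, e) {
    writeLines(sprintf("FAILED at stage '%s': %s", stage,
                       conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  cohort_data <- tryCatch({
    if (!is.null(config$manifest_path)) read_cohort(config$manifest_path)
    else make_cohort(config$cohort)
  }, error = function(e) fail("cohort", e))
  labels <- cohort_data$manifest$group
  glv <- levels(factor(labels))
  patient <- glv[2]; control <- glv[1]
  stage_log("cohort", sprintf("%d subjects (%s)", length(labels),
                              paste(glv, collapse = " vs ")), t0)

  bundle <- list(manifest = cohort_data$manifest)
  for (method in config$methods) {
    mdir <- file.path(config$out_dir, tolower(method))
    dir.create(mdir, showWarnings = FALSE)
    W <- tryCatch(cohort_connectivity(cohort_data, method,
                                      order = config$order),
                  error = function(e) fail(paste0(method, ":connect"), e))
    for (i in seq_along(W))
      write_conn_matrix(W[[i]], file.path(mdir,
        paste0(cohort_data$manifest$subject_id[i], "_", tolower(method),
               ".tsv")),
        extra = list(subject_id = cohort_data$manifest$subject_id[i],
                     order = if (method == "GCA") config$order else NA))
    stage_log("connect", sprintf("%s matrices", method), t0)

    scan <- tryCatch(select_threshold(W, config$grid),
                     error = function(e) fail(paste0(method, ":threshold"), e))
    write_threshold_scan(scan, file.path(mdir, "threshold_scan.csv"))
    B <- lapply(W, proportional_binarize, psw = scan$selected_psw)
    for (i in seq_along(B))
      utils::write.table(B[[i]]$adjacency, file.path(mdir,
        paste0(cohort_data$manifest$subject_id[i], "_binary.tsv")),
        sep = "\t", row.names = FALSE, col.names = FALSE)
    stage_log("threshold", sprintf("%s PSW = %.2f", method,
                                   scan$selected_psw), t0)

    feats <- tryCatch(cohort_features(B, config$ndc_mode),
                      error = function(e) fail(paste0(method, ":metrics"), e))
    ftab <- data.frame(subject_id = cohort_data$manifest$subject_id,
                       group = labels, feats, check.names = FALSE)
    utils::write.csv(ftab, file.path(mdir, "features.csv"),
                     row.names = FALSE)
    tests <- group_test_table(feats, labels, patient, config$alpha)
    utils::write.csv(tests, file.path(mdir, "group_tests.csv"),
                     row.names = FALSE)
    stage_log("metrics", sprintf("%s %d features", method, ncol(feats)), t0)

    Wp <- group_mean_matrix(W[labels == patient])
    Wc <- group_mean_matrix(W[labels == control])
    hub <- if (method == "GCA") {
      hub_consensus(top_connections(Wp, config$hub_k_edges),
                    dissimilar_connections(Wp, Wc, config$hub_k_edges),
                    out_strength_ranking(Wp, config$hub_k_regions),
                    out_strength_dissimilarity(Wp, Wc,
                                               config$hub_k_regions))
    } else NULL
    if (!is.null(hub)) write_hub_report(hub, mdir)
    stage_log("hubs", method, t0)

    report <- tryCatch(
      classify_cohort(feats, labels, config$alpha, config$train_frac,
                      config$seed, config$paper_mode, positive = patient),
      error = function(e) fail(paste0(method, ":classify"), e))
    jsonlite::write_json(unclass(report)[c("accuracy", "precision",
                                           "recall", "f1", "kappa",
                                           "roc_auc",
                                           "n_features_selected")],
                         file.path(mdir, "classification.json"),
                         auto_unbox = TRUE, digits = NA)
    stage_log("classify", sprintf("%s AUC %.3f", method, report$roc_auc),
              t0)
    bundle[[method]] <- list(connectivity = W, scan = scan, networks = B,
                             features = ftab, tests = tests, hubs = hub,
                             classification = report,
                             avg_strength = vapply(
                               W, average_connection_strength, numeric(1)))
  }
  run_manifest <- list(config_hash = config_hash(config),
                       seed = config$seed, methods = config$methods,
                       order = config$order,
                       n_subjects = length(labels),
                       package_version =
                         as.character(utils::packageVersion("gcnet")),
                       r_version = R.version.string)
  jsonlite::write_json(run_manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE)
  invisible(bundle)
}
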