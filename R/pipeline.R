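# End-to-end pipeline: similarity gating -> thresholds -> triage ->
# screen validation -> pharmacophore screening, driven by one config.
#
# Stages are composable: a stage runs when its inputs are configured and is
# skipped (and recorded as skipped) otherwise. All artifacts are plain CSV /
# JSON; a manifest records inputs, config and seed for reproducibility.

#' Build a pipeline configuration
#'
#' @param benchmark Path to the FDA-drug benchmark score CSV (enables the
#'   thresholds stage).
#' @param candidates Path (or named vector of paths) to candidate score CSVs
#'   to triage.
#' @param query_library,drug_library Paths to SMILES libraries for the
#'   similarity stage.
#' @param drug_target_map Path to a `drug_id,target_id` CSV.
#' @param screen_scores Path to a labeled `id,score,active` CSV for EF/ROC
#'   validation.
#' @param pharmacophore Path to a pharmacophore model JSON.
#' @param pose_library Path to a multi-molecule SDF of conformers to screen
#'   against the pharmacophore.
#' @param out_dir Output directory (created if missing).
#' @param alpha Significance level for soft thresholds.
#' @param override_targets Targets given category-specific affinity
#'   thresholds.
#' @param ap_min,maccs_min Similarity-gate thresholds.
#' @param top_pct Percentage for the enrichment factor.
#' @param seed Integer seed recorded in the manifest and used by any
#'   stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(benchmark = NULL, candidates = NULL,
                            query_library = NULL, drug_library = NULL,
                            drug_target_map = NULL, screen_scores = NULL,
                            pharmacophore = NULL, pose_library = NULL,
                            out_dir = "kinscreen_out", alpha = 0.05,
                            override_targets = NULL,
                            ap_min = 0.237, maccs_min = 0.528,
                            top_pct = 5, seed = 1L) {
  cfg <- list(benchmark = benchmark, candidates = candidates,
              query_library = query_library, drug_library = drug_library,
              drug_target_map = drug_target_map, screen_scores = screen_scores,
              pharmacophore = pharmacophore, pose_library = pose_library,
              out_dir = out_dir, alpha = alpha,
              override_targets = override_targets,
              ap_min = ap_min, maccs_min = maccs_min,
              top_pct = top_pct, seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#' @param path Config file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  stopifnot(file.exists(path))
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(pipeline_config, obj)
}

.require_path <- function(path, what) {
  if (!is.null(path) && !all(file.exists(path)))
    stop(what, " file not found: ", paste(path[!file.exists(path)],
                                          collapse = ", "), call. = FALSE)
  path
}

#' Run the screening pipeline
#'
#' Executes the configured stages in order (similarity, thresholds, triage,
#' validation, pharmacophore), writing one artifact per stage into
#' `out_dir` plus a `manifest.json` describing the run.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the per-stage results and artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  artifacts <- list()
  stages <- character(0)

  # -- similarity ------------------------------------------------------------
  if (!is.null(config$query_library) && !is.null(config$drug_library) &&
      !is.null(config$drug_target_map)) {
    .require_path(config$query_library, "Query library")
    .require_path(config$drug_library, "Drug library")
    .require_path(config$drug_target_map, "Drug-target map")
    query <- read_smiles_library(config$query_library)
    drugs <- read_smiles_library(config$drug_library)
    map <- readr::read_csv(config$drug_target_map, show_col_types = FALSE,
                           progress = FALSE)
    hyp <- propose_targets(query, drugs, map,
                           gate_config(config$ap_min, config$maccs_min))
    out <- dplyr::mutate(hyp, proposed_targets = vapply(
      .data$proposed_targets, paste, character(1), collapse = ";"))
    path <- file.path(config$out_dir, "hypotheses.csv")
    readr::write_csv(out, path)
    results$hypotheses <- hyp; artifacts$hypotheses <- path
    stages <- c(stages, "similarity")
  }

  # -- thresholds ------------------------------------------------------------
  thresholds <- NULL
  if (!is.null(config$benchmark)) {
    .require_path(config$benchmark, "Benchmark")
    bench <- read_score_table(config$benchmark)
    thresholds <- derive_thresholds(bench, threshold_config(config$alpha),
                                    override_targets = config$override_targets)
    path <- file.path(config$out_dir, "thresholds.json")
    write_thresholds(thresholds, path)
    results$thresholds <- thresholds; artifacts$thresholds <- path
    stages <- c(stages, "thresholds")
  }

  # -- triage ----------------------------------------------------------------
  if (!is.null(config$candidates)) {
    if (is.null(thresholds))
      stop("Triage stage requires a benchmark to derive thresholds from",
           call. = FALSE)
    .require_path(config$candidates, "Candidate score")
    cand <- dplyr::bind_rows(lapply(config$candidates, read_score_table))
    dec <- triage_table(cand, thresholds)
    path <- file.path(config$out_dir, "triage.csv")
    readr::write_csv(tibble::as_tibble(dec), path)
    results$triage <- dec; artifacts$triage <- path
    stages <- c(stages, "triage")
  }

  # -- validation metrics ----------------------------------------------------
  if (!is.null(config$screen_scores)) {
    .require_path(config$screen_scores, "Screen score")
    screen <- readr::read_csv(config$screen_scores, show_col_types = FALSE,
                              progress = FALSE)
    ef <- enrichment_factor(screen, x_pct = config$top_pct)
    roc <- roc_auc(screen)
    path <- file.path(config$out_dir, "metrics.json")
    jsonlite::write_json(list(ef = ef$ef, x_pct = ef$x_pct,
                              actives_x = ef$actives_x,
                              dataset_x = ef$dataset_x, auc = roc$auc),
                         path, auto_unbox = TRUE, digits = NA)
    results$enrichment <- ef; results$roc <- roc; artifacts$metrics <- path
    stages <- c(stages, "validation")
  }

  # -- pharmacophore screen --------------------------------------------------
  if (!is.null(config$pharmacophore) && !is.null(config$pose_library)) {
    .require_path(config$pharmacophore, "Pharmacophore model")
    .require_path(config$pose_library, "Pose library")
    model <- read_pharmacophore(config$pharmacophore)
    blocks <- .sdf_split_blocks(readLines(config$pose_library, warn = FALSE))
    hits <- list()
    for (k in seq_along(blocks)) {
      mol <- .sdf_parse_block(blocks[[k]])
      m <- match_model(model, perceive_features(mol))
      if (!is.null(m) && isTRUE(m$matched))
        hits[[length(hits) + 1L]] <- tibble::tibble(
          id = if (nzchar(mol$name)) mol$name else sprintf("mol%03d", k),
          n_matched = m$n_matched, feature_rmsd = m$feature_rmsd)
    }
    ranked <- rank_hits(dplyr::bind_rows(hits))
    path <- file.path(config$out_dir, "pharmacophore_hits.csv")
    readr::write_csv(ranked, path)
    results$pharmacophore_hits <- ranked; artifacts$pharmacophore <- path
    stages <- c(stages, "pharmacophore")
  }

  # -- manifest --------------------------------------------------------------
  manifest <- list(
    package = "kinscreen",
    version = as.character(utils::packageVersion("kinscreen")),
    seed = config$seed,
    stages = stages,
    config = config[!vapply(config, is.null, logical(1))],
    artifacts = artifacts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(results = results, artifacts = artifacts, stages = stages,
                 manifest = manifest))
}
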