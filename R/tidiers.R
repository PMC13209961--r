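# broom-style tidy()/glance() methods for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a threshold set
#'
#' @param x A `threshold_set`.
#' @param ... Unused.
#' @return A tibble with one row per (metric, bound kind), columns `metric`,
#'   `bound` (`"soft"`/`"hard"`), `value`, `direction` (`"<="`/`">="`).
#' @exportS3Method generics::tidy
tidy.threshold_set <- function(x, ...) {
  dir <- c(affinity = "<=", cnn_pose_score = ">=", cnn_affinity = ">=")
  rows <- list()
  for (bound in c("soft", "hard")) {
    b <- x[[bound]]
    if (is.null(b)) next
    rows[[bound]] <- tibble::tibble(
      metric = names(dir), bound = bound,
      value = as.numeric(unlist(b[names(dir)])),
      direction = unname(dir)
    )
  }
  if (length(x$category_overrides))
    rows$overrides <- tibble::tibble(
      metric = "affinity",
      bound = paste0("soft[", names(x$category_overrides), "]"),
      value = as.numeric(unlist(x$category_overrides)),
      direction = "<="
    )
  dplyr::bind_rows(rows)
}

#' @rdname tidy.threshold_set
#' @exportS3Method generics::glance
glance.threshold_set <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, n = x$n,
                 n_overrides = length(x$category_overrides))
}

#' Tidy a benchmark summary
#'
#' @param x A `benchmark_summary`.
#' @param ... Unused.
#' @return The per-target means tibble.
#' @exportS3Method generics::tidy
tidy.benchmark_summary <- function(x, ...) x$per_target

#' @rdname tidy.benchmark_summary
#' @exportS3Method generics::glance
glance.benchmark_summary <- function(x, ...) {
  ov <- x$overall
  tibble::tibble(
    n_total = x$n_total, n_targets = nrow(x$per_target),
    mean_affinity = ov$mean[ov$metric == "affinity"],
    min_affinity = ov$min[ov$metric == "affinity"],
    max_affinity = ov$max[ov$metric == "affinity"],
    mean_pose = ov$mean[ov$metric == "cnn_pose_score"],
    min_pose = ov$min[ov$metric == "cnn_pose_score"],
    mean_cnn_affinity = ov$mean[ov$metric == "cnn_affinity"],
    min_cnn_affinity = ov$min[ov$metric == "cnn_affinity"]
  )
}

#' Summarize a triage run
#'
#' @param x A tibble returned by [triage_table()].
#' @param ... Unused.
#' @return One-row tibble with `n`, `n_accepted`, `n_rejected`,
#'   `n_hard_violations`.
#' @exportS3Method generics::glance
glance.triage_table <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    n_accepted = sum(x$accepted),
    n_rejected = sum(!x$accepted),
    n_hard_violations = sum(nzchar(x$hard_violations))
  )
}

#' Tidy an enrichment result
#'
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return One-row tibble with the EF and its defining counts.
#' @exportS3Method generics::tidy
tidy.enrichment_result <- function(x, ...) {
  tibble::tibble(ef = x$ef, x_pct = x$x_pct, actives_x = x$actives_x,
                 dataset_x = x$dataset_x, actives_total = x$actives_total,
                 dataset_total = x$dataset_total,
                 ranking_metric = x$ranking_metric)
}

#' Tidy a ROC result
#'
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return The curve tibble (`fpr`, `tpr`).
#' @exportS3Method generics::tidy
tidy.roc_result <- function(x, ...) x$curve

#' @rdname tidy.roc_result
#' @exportS3Method generics::glance
glance.roc_result <- function(x, ...) tibble::tibble(auc = x$auc)

#' Tidy a pose comparison
#'
#' @param x A `pose_comparison`.
#' @param ... Unused.
#' @return One-row tibble with `rmsd`, `n_atoms`, `mode`, `quality`.
#' @exportS3Method generics::tidy
tidy.pose_comparison <- function(x, ...) {
  tibble::tibble(rmsd = x$rmsd, n_atoms = x$n_atoms, mode = x$mode,
                 quality = x$quality)
}
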