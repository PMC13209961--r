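# Benchmark statistics: per-target and pooled summaries of an FDA-drug
# docking benchmark, and derivation of the acceptance thresholds.
#
# Two kinds of thresholds parameterize the triage rule:
#  * soft -- one-sided Student-t confidence limits at level 1 - alpha over the
#    pooled benchmark: an upper limit for affinity (lower is better) and lower
#    limits for CNN pose score and CNN affinity (higher is better);
#  * hard -- the benchmark extremes (max affinity, min pose, min CNN affinity):
#    no candidate may score worse than the worst approved drug.

METRICS <- c("affinity", "cnn_pose_score", "cnn_affinity")

#' Summarize a docking benchmark table
#'
#' Arithmetic means per biological target and pooled mean/min/max per metric.
#'
#' @param benchmark A validated score tibble (see [score_table()]).
#' @return A `benchmark_summary`: list with `per_target` (tibble of per-target
#'   means and n), `overall` (tibble of mean/min/max per metric) and `n_total`.
#' @export
summarize_benchmark <- function(benchmark) {
  benchmark <- score_table(benchmark)
  if (nrow(benchmark) == 0L) stop("Benchmark table is empty", call. = FALSE)
  per_target <- benchmark |>
    dplyr::group_by(.data$target_id) |>
    dplyr::summarise(
      mean_affinity = mean(.data$affinity),
      mean_pose = mean(.data$cnn_pose_score),
      mean_cnn_affinity = mean(.data$cnn_affinity),
      n = dplyr::n(),
      .groups = "drop"
    )
  overall <- tibble::tibble(
    metric = METRICS,
    mean = vapply(METRICS, function(m) mean(benchmark[[m]]), numeric(1),
                  USE.NAMES = FALSE),
    min = vapply(METRICS, function(m) min(benchmark[[m]]), numeric(1),
                 USE.NAMES = FALSE),
    max = vapply(METRICS, function(m) max(benchmark[[m]]), numeric(1),
                 USE.NAMES = FALSE)
  )
  structure(list(per_target = per_target, overall = overall,
                 n_total = nrow(benchmark)),
            class = "benchmark_summary")
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat(sprintf("<benchmark_summary> %d records, %d targets\n",
              x$n_total, nrow(x$per_target)))
  print(x$overall)
  invisible(x)
}

#' Threshold-derivation configuration
#'
#' @param alpha One-sided significance level in (0, 0.5); the confidence level
#'   of the soft thresholds is `1 - alpha`.
#' @param method Quantile for the one-sided bound: `"normal"` (the default;
#'   the large-sample limit routinely used at benchmark sizes of ~50) or
#'   `"student_t"` (exact small-sample bound, slightly wider).
#' @return A `threshold_config` list.
#' @export
threshold_config <- function(alpha = 0.05, method = c("normal", "student_t")) {
  stopifnot(alpha > 0, alpha < 0.5)
  method <- match.arg(method)
  structure(list(alpha = alpha, method = method), class = "threshold_config")
}

.soft_bounds <- function(benchmark, alpha, method = "normal") {
  n <- nrow(benchmark)
  if (n < 2)
    stop("Soft thresholds need at least 2 benchmark records (SD undefined)",
         call. = FALSE)
  tq <- if (identical(method, "student_t")) stats::qt(1 - alpha, df = n - 1)
    else stats::qnorm(1 - alpha)
  se <- function(v) stats::sd(v) / sqrt(n)
  list(
    affinity = mean(benchmark$affinity) + tq * se(benchmark$affinity),
    cnn_pose_score = mean(benchmark$cnn_pose_score) - tq * se(benchmark$cnn_pose_score),
    cnn_affinity = mean(benchmark$cnn_affinity) - tq * se(benchmark$cnn_affinity)
  )
}

#' Derive soft (confidence-limit) thresholds
#'
#' One-sided confidence bounds on the pooled benchmark means at level
#' `1 - alpha`: the upper confidence limit of the mean for affinity and the
#' lower limits for CNN pose score and CNN affinity, each
#' `mean +/- q(1 - alpha) * s / sqrt(n)` with the sample standard deviation
#' and the quantile chosen by `config$method` (standard normal by default;
#' Student t with `n - 1` degrees of freedom as the small-sample option).
#'
#' @param benchmark A score tibble with at least two rows.
#' @param config A [threshold_config()].
#' @return A `threshold_set` with only the soft fields populated.
#' @export
derive_soft_thresholds <- function(benchmark, config = threshold_config()) {
  benchmark <- score_table(benchmark)
  soft <- .soft_bounds(benchmark, config$alpha, config$method)
  new_threshold_set(soft = soft, hard = NULL, alpha = config$alpha,
                    n = nrow(benchmark))
}

#' Derive hard (extreme-value) thresholds
#'
#' The benchmark extremes: maximum (weakest) affinity, minimum CNN pose score,
#' minimum CNN affinity. A candidate scoring beyond any of these does worse
#' than the worst approved drug in the benchmark and is never accepted.
#'
#' @param benchmark A score tibble with at least one row.
#' @return A `threshold_set` with only the hard fields populated.
#' @export
derive_hard_thresholds <- function(benchmark) {
  benchmark <- score_table(benchmark)
  if (nrow(benchmark) == 0L) stop("Benchmark table is empty", call. = FALSE)
  hard <- list(
    affinity = max(benchmark$affinity),
    cnn_pose_score = min(benchmark$cnn_pose_score),
    cnn_affinity = min(benchmark$cnn_affinity)
  )
  new_threshold_set(soft = NULL, hard = hard, alpha = NA_real_,
                    n = nrow(benchmark))
}

#' Derive the complete threshold set
#'
#' Convenience wrapper computing soft and hard thresholds from one benchmark,
#' optionally with category-specific affinity overrides (see
#' [category_override()]).
#'
#' @param benchmark A score tibble.
#' @param config A [threshold_config()].
#' @param override_targets Character vector of target ids for which the soft
#'   affinity threshold is replaced by that target's mean benchmark affinity.
#' @return A complete `threshold_set`.
#' @export
derive_thresholds <- function(benchmark, config = threshold_config(),
                              override_targets = NULL) {
  benchmark <- score_table(benchmark)
  ts <- new_threshold_set(
    soft = .soft_bounds(benchmark, config$alpha, config$method),
    hard = list(affinity = max(benchmark$affinity),
                cnn_pose_score = min(benchmark$cnn_pose_score),
                cnn_affinity = min(benchmark$cnn_affinity)),
    alpha = config$alpha, n = nrow(benchmark)
  )
  for (tg in override_targets)
    ts <- add_category_override(ts, category_override(benchmark, tg), tg)
  ts
}

#' Construct a threshold set from known values
#'
#' Builds the triage rule's parameters directly, e.g. from previously
#' published limits, rather than deriving them from a benchmark table.
#'
#' @param affinity_soft,pose_soft,cnn_affinity_soft Soft (confidence-limit)
#'   thresholds: pass is `affinity <= affinity_soft`, `pose >= pose_soft`,
#'   `cnn_affinity >= cnn_affinity_soft`.
#' @param affinity_hard,pose_hard,cnn_affinity_hard Hard (extreme-value)
#'   bounds with the same directions.
#' @param alpha,n Optional provenance metadata.
#' @param category_overrides Named list of per-target soft affinity
#'   replacements.
#' @return A `threshold_set`.
#' @examples
#' threshold_set(-9.00, 0.843, 7.702, -6.82, 0.526, 7.010)
#' @export
threshold_set <- function(affinity_soft, pose_soft, cnn_affinity_soft,
                          affinity_hard, pose_hard, cnn_affinity_hard,
                          alpha = NA_real_, n = NA_integer_,
                          category_overrides = list()) {
  new_threshold_set(
    soft = list(affinity = affinity_soft, cnn_pose_score = pose_soft,
                cnn_affinity = cnn_affinity_soft),
    hard = list(affinity = affinity_hard, cnn_pose_score = pose_hard,
                cnn_affinity = cnn_affinity_hard),
    alpha = alpha, n = n, category_overrides = category_overrides
  )
}

new_threshold_set <- function(soft, hard, alpha, n,
                              category_overrides = list()) {
  if (!is.null(soft) && !is.null(hard)) {
    stopifnot(soft$affinity <= hard$affinity,
              soft$cnn_pose_score >= hard$cnn_pose_score,
              soft$cnn_affinity >= hard$cnn_affinity)
  }
  structure(list(soft = soft, hard = hard, alpha = alpha, n = n,
                 category_overrides = category_overrides),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set>\n")
  if (!is.null(x$soft))
    cat(sprintf("  soft: affinity <= %.2f, pose >= %.3f, CNN affinity >= %.3f  (alpha = %s, n = %d)\n",
                x$soft$affinity, x$soft$cnn_pose_score, x$soft$cnn_affinity,
                format(x$alpha), x$n))
  if (!is.null(x$hard))
    cat(sprintf("  hard: affinity <= %.2f, pose >= %.3f, CNN affinity >= %.3f\n",
                x$hard$affinity, x$hard$cnn_pose_score, x$hard$cnn_affinity))
  if (length(x$category_overrides))
    cat("  overrides:",
        paste(sprintf("%s: affinity <= %.2f", names(x$category_overrides),
                      unlist(x$category_overrides)), collapse = "; "), "\n")
  invisible(x)
}

#' Category-specific soft affinity threshold
#'
#' For targets where generic docking systematically underestimates affinity
#' (large conformational shifts the scoring function cannot see), the pooled
#' soft affinity bound is too strict; the per-target mean benchmark affinity
#' is used instead. Only affinity is ever overridden.
#'
#' @param benchmark A score tibble.
#' @param target_id Target present in the benchmark.
#' @return The target's mean affinity (kcal/mol).
#' @export
category_override <- function(benchmark, target_id) {
  benchmark <- score_table(benchmark)
  rows <- benchmark$target_id == target_id
  if (!any(rows))
    stop("Target not present in benchmark: ", target_id, call. = FALSE)
  mean(benchmark$affinity[rows])
}

#' Register a category override on a threshold set
#'
#' @param thresholds A `threshold_set`.
#' @param value Replacement soft affinity threshold (kcal/mol).
#' @param target_id Target the override applies to.
#' @return The updated `threshold_set`.
#' @export
add_category_override <- function(thresholds, value, target_id) {
  stopifnot(inherits(thresholds, "threshold_set"), is.numeric(value),
            is.character(target_id), length(target_id) == 1L)
  thresholds$category_overrides[[target_id]] <- unname(value)
  thresholds
}

#' Write thresholds to JSON
#' @param thresholds A `threshold_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "threshold_set"))
  obj <- list(
    alpha = thresholds$alpha, n = thresholds$n,
    soft = thresholds$soft, hard = thresholds$hard,
    category_overrides = thresholds$category_overrides
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read thresholds from JSON
#' @param path JSON file written by [write_thresholds()].
#' @return A `threshold_set`.
#' @export
read_thresholds <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ovr <- as.list(obj$category_overrides)
  new_threshold_set(soft = obj$soft, hard = obj$hard,
                    alpha = obj$alpha %||% NA_real_,
                    n = obj$n %||% NA_integer_,
                    category_overrides = ovr)
}
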