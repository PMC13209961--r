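# ggplot2 visualisations for the main result types.

#' Plot a ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False-positive rate", y = "True-positive rate",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot benchmark score distributions with thresholds
#'
#' One panel per metric showing the benchmark distribution with the soft
#' (dashed) and hard (dotted) thresholds.
#'
#' @param benchmark A score tibble.
#' @param thresholds A `threshold_set` (optional).
#' @return A ggplot.
#' @export
plot_benchmark <- function(benchmark, thresholds = NULL) {
  benchmark <- score_table(benchmark)
  long <- tidyr::pivot_longer(benchmark, dplyr::all_of(METRICS),
                              names_to = "metric", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 15, fill = "#74add1", colour = "white") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "count") +
    ggplot2::theme_minimal()
  if (!is.null(thresholds)) {
    th <- tidy(thresholds)
    th <- th[th$bound %in% c("soft", "hard"), , drop = FALSE]
    p <- p + ggplot2::geom_vline(
      data = th,
      ggplot2::aes(xintercept = .data$value, linetype = .data$bound),
      colour = "#b2182b") +
      ggplot2::scale_linetype_manual(values = c(soft = "dashed",
                                                hard = "dotted"))
  }
  p
}

#' Plot triage decisions in metric space
#'
#' Affinity vs CNN pose score, points sized by CNN affinity and coloured by
#' the triage verdict.
#'
#' @param decisions A tibble from [triage_table()].
#' @return A ggplot.
#' @export
plot_triage <- function(decisions) {
  ggplot2::ggplot(decisions,
                  ggplot2::aes(x = .data$affinity, y = .data$cnn_pose_score,
                               colour = .data$accepted,
                               size = .data$cnn_affinity)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#1a9850",
                                            `FALSE` = "#d73027")) +
    ggplot2::labs(x = "Affinity (kcal/mol)", y = "CNN pose score",
                  colour = "accepted", size = "CNN affinity") +
    ggplot2::theme_minimal()
}

#' Plot enrichment as an accumulation curve
#'
#' Fraction of actives recovered against fraction of the ranked list
#' screened, with the random-selection diagonal.
#'
#' @param scores Data frame with `id`, `score`, `active`.
#' @param direction `"desc"` or `"asc"` ranking direction.
#' @return A ggplot.
#' @export
plot_enrichment <- function(scores, direction = c("desc", "asc")) {
  direction <- match.arg(direction)
  ord <- order(if (direction == "desc") -scores$score else scores$score,
               as.character(scores$id))
  active <- as.logical(scores$active)[ord]
  df <- tibble::tibble(
    screened = seq_along(active) / length(active),
    recovered = cumsum(active) / sum(active)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$screened, y = .data$recovered)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::labs(x = "Fraction of library screened",
                  y = "Fraction of actives recovered") +
    ggplot2::theme_minimal()
}
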