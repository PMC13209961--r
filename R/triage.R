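# Candidate triage: the two-criteria acceptance rule applied to docking
# records.
#
#  (i)  a candidate must meet at least two of the three soft thresholds
#       (affinity <= soft, CNN pose score >= soft, CNN affinity >= soft);
#  (ii) any metric that misses its soft threshold must still satisfy the
#       corresponding hard bound -- a single hard violation rejects.
#
# All comparisons are inclusive and operate on unrounded values. A third,
# qualitative criterion (visual inspection of binding interactions) is not
# automated; an `interaction_note` column carries curator text through.

.soft_for <- function(thresholds, target_id) {
  soft <- thresholds$soft
  if (!is.null(target_id) && !is.na(target_id) &&
      target_id %in% names(thresholds$category_overrides))
    soft$affinity <- thresholds$category_overrides[[target_id]]
  soft
}

.evaluate_one <- function(affinity, cnn_pose_score, cnn_affinity,
                          thresholds, target_id = NA_character_) {
  soft <- .soft_for(thresholds, target_id)
  hard <- thresholds$hard
  soft_pass <- c(
    affinity = affinity <= soft$affinity,
    cnn_pose_score = cnn_pose_score >= soft$cnn_pose_score,
    cnn_affinity = cnn_affinity >= soft$cnn_affinity
  )
  hard_pass <- c(
    affinity = affinity <= hard$affinity,
    cnn_pose_score = cnn_pose_score >= hard$cnn_pose_score,
    cnn_affinity = cnn_affinity >= hard$cnn_affinity
  )
  hard_violation <- !soft_pass & !hard_pass
  accepted <- sum(soft_pass) >= 2L && !any(hard_violation)
  rationale <- if (accepted) {
    sprintf("accepted: %d/3 soft thresholds met (%s), no hard violation",
            sum(soft_pass), paste(names(soft_pass)[soft_pass], collapse = ", "))
  } else if (any(hard_violation)) {
    sprintf("rejected: hard violation on %s",
            paste(names(hard_violation)[hard_violation], collapse = ", "))
  } else {
    sprintf("rejected: only %d/3 soft thresholds met", sum(soft_pass))
  }
  list(soft_passes = names(soft_pass)[soft_pass],
       hard_violations = names(hard_violation)[hard_violation],
       accepted = accepted, rationale = rationale)
}

#' Evaluate one docking record against a threshold set
#'
#' @param affinity Binding affinity (kcal/mol; more negative is stronger).
#' @param cnn_pose_score CNN pose score in \[0, 1\].
#' @param cnn_affinity CNN affinity (positive).
#' @param thresholds A complete `threshold_set` (soft and hard fields).
#' @param target_id Optional target; if it has a registered category override,
#'   that value replaces the soft affinity threshold.
#' @return A `triage_decision`: list with `soft_passes`, `hard_violations`,
#'   `accepted` and a human-readable `rationale`.
#' @export
triage_evaluate <- function(affinity, cnn_pose_score, cnn_affinity, thresholds,
                            target_id = NA_character_) {
  stopifnot(inherits(thresholds, "threshold_set"),
            !is.null(thresholds$soft), !is.null(thresholds$hard),
            is.finite(affinity), is.finite(cnn_pose_score),
            is.finite(cnn_affinity))
  structure(.evaluate_one(affinity, cnn_pose_score, cnn_affinity,
                          thresholds, target_id),
            class = "triage_decision")
}

#' @export
print.triage_decision <- function(x, ...) {
  cat("<triage_decision>", x$rationale, "\n")
  invisible(x)
}

#' Triage a table of candidate docking records
#'
#' Applies [triage_evaluate()] to every row, preserving input order.
#'
#' @param candidates A score tibble (see [score_table()]); an optional
#'   `interaction_note` column is carried through unchanged.
#' @param thresholds A complete `threshold_set`.
#' @return A tibble with the input columns plus `soft_passes` and
#'   `hard_violations` (comma-joined), `n_soft_passes`, `accepted` and
#'   `rationale`. Attribute `n_accepted` holds the summary count; see also
#'   [glance.triage_table()].
#' @export
triage_table <- function(candidates, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  candidates <- score_table(candidates)
  if (nrow(candidates) == 0L) {
    out <- dplyr::mutate(candidates, soft_passes = character(),
                         hard_violations = character(),
                         n_soft_passes = integer(),
                         accepted = logical(), rationale = character())
  } else {
    dec <- purrr::pmap(
      candidates[, c("affinity", "cnn_pose_score", "cnn_affinity", "target_id")],
      function(affinity, cnn_pose_score, cnn_affinity, target_id)
        .evaluate_one(affinity, cnn_pose_score, cnn_affinity, thresholds,
                      target_id)
    )
    out <- candidates
    out$soft_passes <- vapply(dec, function(d)
      paste(d$soft_passes, collapse = ","), character(1))
    out$hard_violations <- vapply(dec, function(d)
      paste(d$hard_violations, collapse = ","), character(1))
    out$n_soft_passes <- vapply(dec, function(d)
      length(d$soft_passes), integer(1))
    out$accepted <- vapply(dec, `[[`, logical(1), "accepted")
    out$rationale <- vapply(dec, `[[`, character(1), "rationale")
  }
  class(out) <- c("triage_table", class(out))
  attr(out, "n_accepted") <- sum(out$accepted)
  out
}
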