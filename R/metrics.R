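# Screen validation metrics: symmetry-aware pose RMSD with the 2/3 Angstrom
# quality bands, the enrichment factor, and ROC-AUC.

#' Classify a pose RMSD into docking-quality bands
#'
#' Below 2.0 Angstrom a reproduced pose is consistent with the reference;
#' between 2.0 and 3.0 it deviates while keeping the intended orientation;
#' beyond 3.0 it is considered inaccurate.
#'
#' @param rmsd Non-negative RMSD in Angstrom (vectorized).
#' @return Factor with levels `consistent`, `deviated`, `inaccurate`.
#' @export
classify_rmsd <- function(rmsd) {
  stopifnot(is.numeric(rmsd), all(rmsd >= 0))
  cut(rmsd, breaks = c(-Inf, 2.0, 3.0, Inf),
      labels = c("consistent", "deviated", "inaccurate"),
      right = FALSE) |>
    (\(f) {
      # the middle band is inclusive on both ends: exactly 3.0 is "deviated"
      f[rmsd == 3.0] <- "deviated"
      f
    })()
}

# ---- rigid superposition ----------------------------------------------------

# Kabsch least-squares rotation with reflection guard. Returns the rotation
# applied to centered `moving` that best fits centered `fixed`.
.kabsch <- function(fixed, moving) {
  cf <- colMeans(fixed); cm <- colMeans(moving)
  A <- sweep(moving, 2, cm)
  B <- sweep(fixed, 2, cf)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  list(R = R, center_moving = cm, center_fixed = cf)
}

# apply a .kabsch() transform to a coordinate matrix
.apply_transform <- function(xyz, tr) {
  sweep(sweep(xyz, 2, tr$center_moving) %*% t(tr$R), 2, tr$center_fixed, `+`)
}

.rmsd_of <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# ---- automorphism enumeration ----------------------------------------------

# All automorphisms of the heavy-atom bond graph, colored by element; returns
# a list of permutations. Enumeration caps at `cap`; beyond it, falls back to
# the identity mapping (documented behavior).
.mol_automorphisms <- function(mol, cap = 10000L) {
  n <- nrow(mol$atoms)
  if (n == 0L) return(list(integer(0)))
  if (nrow(mol$bonds) == 0L) {
    # no bonds: any element-preserving permutation; enumerate only if tiny
    if (n > 6L) return(list(seq_len(n)))
  }
  g <- igraph::graph_from_data_frame(
    d = if (nrow(mol$bonds)) mol$bonds[, c("i", "j")] else
      data.frame(i = integer(), j = integer()),
    directed = FALSE, vertices = data.frame(name = seq_len(n))
  )
  colors <- as.integer(factor(mol$atoms$element))
  maps <- tryCatch(
    igraph::graph.get.isomorphisms.vf2(g, g, vertex.color1 = colors,
                                       vertex.color2 = colors),
    error = function(e) NULL
  )
  if (is.null(maps) || !length(maps)) return(list(seq_len(n)))
  perms <- lapply(maps, function(m) as.integer(igraph::V(g)$name)[as.integer(m)])
  if (length(perms) > cap) {
    warning("Automorphism count exceeds cap (", length(perms), " > ", cap,
            "); using identity mapping only", call. = FALSE)
    return(list(seq_len(n)))
  }
  perms
}

#' Symmetry-aware pose RMSD
#'
#' Heavy-atom RMSD between a reference conformer and a docked/perturbed pose
#' of the same molecule, minimized over the automorphisms of the element-
#' colored bond graph so that topologically equivalent atoms (e.g. the two
#' ortho carbons of a phenyl ring) are matched correctly.
#'
#' @param ref,pose `mol_graph` objects with conformers; they must share the
#'   same molecular graph (element multiset and bond topology).
#' @param mode `"in_place"` (default; no superposition -- the re-/cross-docking
#'   convention, both poses in the receptor frame) or `"superposed"`
#'   (additionally minimized over rigid motions by least-squares).
#' @param max_automorphisms Enumeration cap.
#' @return A `pose_comparison`: list with `rmsd`, `n_atoms`, `mapping`
#'   (pose index for each reference atom), `mode` and `quality`
#'   (see [classify_rmsd()]).
#' @export
pose_rmsd <- function(ref, pose, mode = c("in_place", "superposed"),
                      max_automorphisms = 10000L) {
  mode <- match.arg(mode)
  stopifnot(inherits(ref, "mol_graph"), inherits(pose, "mol_graph"))
  n <- nrow(ref$atoms)
  if (n != nrow(pose$atoms) ||
      !identical(sort(ref$atoms$element), sort(pose$atoms$element)))
    stop("Reference and pose do not share a molecular graph ",
         "(different element composition)", call. = FALSE)
  same_graph <- identical(ref$atoms$element, pose$atoms$element) &&
    identical(ref$bonds[, c("i", "j", "order")], pose$bonds[, c("i", "j", "order")])
  if (!same_graph) {
    # allow differently-ordered inputs if an isomorphism exists
    iso <- .match_graphs(ref, pose)
    if (is.null(iso))
      stop("Reference and pose do not share a molecular graph ",
           "(no element-preserving bond isomorphism)", call. = FALSE)
    pose <- .reorder_mol(pose, iso)
  }
  if (mode == "superposed" && n < 3)
    stop("Superposed RMSD needs at least 3 atoms", call. = FALSE)
  xr <- mol_coords(ref); xp <- mol_coords(pose)
  perms <- .mol_automorphisms(ref, cap = max_automorphisms)
  best <- Inf; best_perm <- seq_len(n)
  for (p in perms) {
    xpp <- xp[p, , drop = FALSE]
    r <- if (mode == "in_place") .rmsd_of(xr, xpp) else {
      tr <- .kabsch(xr, xpp)
      .rmsd_of(xr, .apply_transform(xpp, tr))
    }
    if (r < best) { best <- r; best_perm <- p }
  }
  structure(list(rmsd = best, n_atoms = n, mapping = best_perm, mode = mode,
                 quality = as.character(classify_rmsd(best))),
            class = "pose_comparison")
}

#' @export
print.pose_comparison <- function(x, ...) {
  cat(sprintf("<pose_comparison> rmsd = %.3f A over %d atoms (%s, %s)\n",
              x$rmsd, x$n_atoms, x$mode, x$quality))
  invisible(x)
}

# one isomorphism from ref to pose graph (element-colored), or NULL
.match_graphs <- function(ref, pose) {
  mk <- function(mol) igraph::graph_from_data_frame(
    d = if (nrow(mol$bonds)) mol$bonds[, c("i", "j")] else
      data.frame(i = integer(), j = integer()),
    directed = FALSE, vertices = data.frame(name = seq_len(nrow(mol$atoms))))
  lev <- sort(unique(c(ref$atoms$element, pose$atoms$element)))
  c1 <- as.integer(factor(ref$atoms$element, levels = lev))
  c2 <- as.integer(factor(pose$atoms$element, levels = lev))
  m <- tryCatch(
    igraph::graph.subisomorphic.vf2(mk(pose), mk(ref),
                                    vertex.color1 = c2, vertex.color2 = c1),
    error = function(e) NULL
  )
  if (is.null(m) || !isTRUE(m$iso)) return(NULL)
  as.integer(m$map21)
}

.reorder_mol <- function(mol, perm) {
  # perm[i] = index in mol matching reference atom i
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  atoms <- mol$atoms[perm, , drop = FALSE]
  atoms$idx <- seq_len(nrow(atoms))
  bonds <- mol$bonds
  if (nrow(bonds)) { bonds$i <- inv[bonds$i]; bonds$j <- inv[bonds$j] }
  new_mol_graph(atoms, bonds, name = mol$name)
}

# ---- enrichment -------------------------------------------------------------

#' Enrichment factor of a ranked screen
#'
#' How many more actives sit in the top `x_pct` percent of the ranked list
#' than random selection would put there:
#' \deqn{EF_{x\%} = \frac{actives_{x\%} / dataset_{x\%}}
#'                       {actives_{total} / dataset_{total}}}
#' The top slice holds `floor(x_pct * N / 100)` compounds; ties in the ranking
#' score are broken by stable id order.
#'
#' @param scores Data frame with columns `id`, `score` and logical `active`.
#' @param x_pct Percentage of the list inspected, in (0, 100].
#' @param direction `"desc"` if larger scores rank better (pose score, CNN
#'   affinity), `"asc"` if smaller rank better (affinity in kcal/mol).
#' @param ranking_metric Free-text label recorded in the result.
#' @return An `enrichment_result`: list with `ef`, the counts
#'   (`actives_x`, `dataset_x`, `actives_total`, `dataset_total`), `x_pct`
#'   and `ranking_metric`.
#' @export
enrichment_factor <- function(scores, x_pct = 5, direction = c("desc", "asc"),
                              ranking_metric = "score") {
  direction <- match.arg(direction)
  stopifnot(all(c("id", "score", "active") %in% names(scores)),
            x_pct > 0, x_pct <= 100)
  active <- as.logical(scores$active)
  n_total <- nrow(scores)
  a_total <- sum(active)
  if (a_total == 0L) stop("No active compounds in `scores`", call. = FALSE)
  if (a_total == n_total) stop("No inactive compounds in `scores`", call. = FALSE)
  n_x <- floor(x_pct * n_total / 100)
  if (n_x == 0L)
    stop("Top slice is empty: floor(", x_pct, "% of ", n_total, ") = 0",
         call. = FALSE)
  ord <- order(if (direction == "desc") -scores$score else scores$score,
               as.character(scores$id))
  a_x <- sum(active[ord][seq_len(n_x)])
  ef <- (a_x / n_x) / (a_total / n_total)
  structure(list(ef = ef, actives_x = a_x, dataset_x = n_x,
                 actives_total = a_total, dataset_total = n_total,
                 x_pct = x_pct, ranking_metric = ranking_metric),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment> EF(%g%%) = %.3f  [%d/%d actives in top %d of %d]\n",
              x$x_pct, x$ef, x$actives_x, x$actives_total, x$dataset_x,
              x$dataset_total))
  invisible(x)
}

#' Enrichment factor from pre-tabulated counts
#'
#' @param actives_x Actives found in the inspected top slice.
#' @param dataset_x Size of the top slice.
#' @param actives_total,dataset_total Totals for the whole screen.
#' @param x_pct Percentage the slice corresponds to (label only).
#' @return An `enrichment_result`.
#' @export
enrichment_from_counts <- function(actives_x, dataset_x, actives_total,
                                   dataset_total, x_pct = NA_real_) {
  stopifnot(actives_x <= dataset_x, actives_x <= actives_total,
            dataset_x <= dataset_total, actives_total >= 1)
  ef <- (actives_x / dataset_x) / (actives_total / dataset_total)
  structure(list(ef = ef, actives_x = actives_x, dataset_x = dataset_x,
                 actives_total = actives_total, dataset_total = dataset_total,
                 x_pct = x_pct, ranking_metric = "counts"),
            class = "enrichment_result")
}

# ---- ROC --------------------------------------------------------------------

#' ROC curve and AUC of a labeled screen
#'
#' AUC is computed as the tie-aware rank statistic: the fraction of
#' (active, inactive) pairs ranked correctly, with half credit for ties
#' (equivalently the normalized Mann-Whitney statistic). The curve is the
#' standard threshold sweep from (0, 0) to (1, 1).
#'
#' @inheritParams enrichment_factor
#' @return A `roc_result`: list with `auc` and `curve`
#'   (tibble of `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, direction = c("desc", "asc")) {
  direction <- match.arg(direction)
  stopifnot(all(c("score", "active") %in% names(scores)))
  active <- as.logical(scores$active)
  n_a <- sum(active); n_i <- sum(!active)
  if (n_a == 0L || n_i == 0L)
    stop("ROC needs at least one active and one inactive compound",
         call. = FALSE)
  s <- if (direction == "desc") scores$score else -scores$score
  r <- rank(s, ties.method = "average")
  auc <- (sum(r[active]) - n_a * (n_a + 1) / 2) / (n_a * n_i)
  # threshold sweep (unique score cutoffs, ties grouped)
  ord <- order(-s)
  sa <- active[ord]; ss <- s[ord]
  grp_last <- c(ss[-length(ss)] != ss[-1], TRUE)
  tp <- cumsum(sa)[grp_last]; fp <- cumsum(!sa)[grp_last]
  curve <- tibble::tibble(fpr = c(0, fp / n_i), tpr = c(0, tp / n_a))
  structure(list(auc = auc, curve = curve, direction = direction),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (%d curve points)\n",
              x$auc, nrow(x$curve)))
  invisible(x)
}
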