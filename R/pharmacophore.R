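# Lightweight pharmacophores: feature perception on 3D conformers,
# tolerance-sphere matching with least-squares alignment and RMSD ranking,
# drug-likeness property windows, and the receptor steric filter.
#
# Feature kinds and default tolerance radii (Angstrom):
#   HAC hydrogen-bond acceptor 0.5   HDO hydrogen-bond donor 0.5
#   HPB hydrophobic            1.0   ARO aromatic ring        1.1
#   POS positive charge        0.75  NEG negative charge      0.75
#
# Perception is rule-based on the heavy-atom graph (no external SMARTS
# engine): HAC = N/O with a lone pair, excluding amide N, aromatic N-H and
# positively charged atoms; HDO = O-H / N-H; ARO = centroid of each aromatic
# ring; HPB = centroid of each connected fragment of >= 3 carbons none of
# which touches a heteroatom; POS/NEG = formally charged atoms at the input
# protonation state.

FEATURE_KINDS <- c("HAC", "HDO", "ARO", "HPB", "POS", "NEG")

FEATURE_RADII <- c(HAC = 0.5, HDO = 0.5, ARO = 1.1, HPB = 1.0,
                   POS = 0.75, NEG = 0.75)

.is_amide_n <- function(mol, i) {
  # N bonded to a carbon that carries a double bond to O
  nb <- c(mol$bonds$j[mol$bonds$i == i], mol$bonds$i[mol$bonds$j == i])
  for (c_at in nb[mol$atoms$element[nb] == "C"]) {
    cb <- mol$bonds[(mol$bonds$i == c_at | mol$bonds$j == c_at) &
                      mol$bonds$order == 2L, , drop = FALSE]
    other <- ifelse(cb$i == c_at, cb$j, cb$i)
    if (any(mol$atoms$element[other] == "O")) return(TRUE)
  }
  FALSE
}

#' Perceive pharmacophore features of a 3D conformer
#'
#' @param mol A `mol_graph` with conformer coordinates.
#' @return A tibble of features: `kind`, `x`, `y`, `z`, `radius`, `atoms`
#'   (list-column of contributing atom indices).
#' @export
perceive_features <- function(mol) {
  stopifnot(inherits(mol, "mol_graph"))
  if (nrow(mol$atoms) == 0L)
    stop("Molecule has no heavy atoms / conformer", call. = FALSE)
  at <- mol$atoms
  feats <- list()
  add <- function(kind, xyz, atoms) {
    feats[[length(feats) + 1L]] <<- tibble::tibble(
      kind = kind, x = xyz[1], y = xyz[2], z = xyz[3],
      radius = unname(FEATURE_RADII[kind]), atoms = list(atoms))
  }

  # acceptors and donors
  for (i in seq_len(nrow(at))) {
    el <- at$element[i]
    if (!el %in% c("N", "O")) next
    xyz <- c(at$x[i], at$y[i], at$z[i])
    if (at$n_h[i] >= 1L && at$charge[i] >= 0) add("HDO", xyz, i)
    acceptor <- at$charge[i] <= 0 && (
      el == "O" ||
      (el == "N" && !.is_amide_n(mol, i) && !(at$aromatic[i] && at$n_h[i] > 0L))
    )
    if (acceptor && at$charge[i] == 0 && el == "N" &&
        at$degree[i] + at$n_h[i] >= 4L) acceptor <- FALSE  # no lone pair
    if (acceptor) add("HAC", xyz, i)
  }

  # aromatic ring centroids
  for (ring in mol$rings) {
    if (all(at$aromatic[ring]) && length(ring) %in% c(5L, 6L)) {
      in_ring <- mol$bonds$i %in% ring & mol$bonds$j %in% ring
      if (sum(in_ring) == length(ring))
        add("ARO", c(mean(at$x[ring]), mean(at$y[ring]), mean(at$z[ring])), ring)
    }
  }

  # hydrophobic fragments: non-aromatic carbons with no heteroatom neighbor,
  # components >= 3 (aromatic carbons are carried by their ARO ring feature)
  hetero <- !at$element %in% c("C", "H")
  has_het_nb <- logical(nrow(at))
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      if (hetero[mol$bonds$j[r]]) has_het_nb[mol$bonds$i[r]] <- TRUE
      if (hetero[mol$bonds$i[r]]) has_het_nb[mol$bonds$j[r]] <- TRUE
    }
  }
  apolar <- which(at$element == "C" & !at$aromatic & !has_het_nb)
  if (length(apolar) >= 3L) {
    sub <- mol$bonds[mol$bonds$i %in% apolar & mol$bonds$j %in% apolar, ,
                     drop = FALSE]
    g <- igraph::graph_from_data_frame(
      d = sub[, c("i", "j")], directed = FALSE,
      vertices = data.frame(name = apolar))
    comp <- igraph::components(g)
    for (k in seq_len(comp$no)) {
      members <- apolar[comp$membership == k]
      if (length(members) >= 3L)
        add("HPB", c(mean(at$x[members]), mean(at$y[members]),
                     mean(at$z[members])), members)
    }
  }

  # formal charges
  for (i in which(at$charge > 0)) add("POS", c(at$x[i], at$y[i], at$z[i]), i)
  for (i in which(at$charge < 0)) add("NEG", c(at$x[i], at$y[i], at$z[i]), i)

  if (!length(feats))
    return(tibble::tibble(kind = character(), x = numeric(), y = numeric(),
                          z = numeric(), radius = numeric(), atoms = list()))
  dplyr::bind_rows(feats)
}

# ---- model ------------------------------------------------------------------

#' Construct a pharmacophore model
#'
#' @param features Tibble with columns `kind` (one of HAC, HDO, ARO, HPB,
#'   POS, NEG), `x`, `y`, `z` and optionally `radius` (defaults by kind).
#' @param name Model name.
#' @param required_count Minimum number of features a hit must match
#'   (default: all of them).
#' @return A `pharmacophore_model`.
#' @export
pharmacophore_model <- function(features, name = "model",
                                required_count = nrow(features)) {
  features <- tibble::as_tibble(features)
  stopifnot(all(c("kind", "x", "y", "z") %in% names(features)),
            nrow(features) >= 2L,
            all(features$kind %in% FEATURE_KINDS),
            required_count >= 1, required_count <= nrow(features))
  if (!"radius" %in% names(features))
    features$radius <- unname(FEATURE_RADII[features$kind])
  stopifnot(all(features$radius > 0),
            all(is.finite(features$x + features$y + features$z)))
  structure(list(name = name, features = features,
                 required_count = as.integer(required_count)),
            class = "pharmacophore_model")
}

#' @export
print.pharmacophore_model <- function(x, ...) {
  comp <- table(x$features$kind)
  cat(sprintf("<pharmacophore_model> %s: %s (match >= %d)\n", x$name,
              paste(sprintf("%d %s", as.integer(comp), names(comp)),
                    collapse = " + "),
              x$required_count))
  invisible(x)
}

#' Write a pharmacophore model to JSON
#' @param model A `pharmacophore_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pharmacophore <- function(model, path) {
  stopifnot(inherits(model, "pharmacophore_model"))
  obj <- list(
    name = model$name,
    required_count = model$required_count,
    features = lapply(seq_len(nrow(model$features)), function(i)
      list(kind = model$features$kind[i],
           center = c(model$features$x[i], model$features$y[i],
                      model$features$z[i]),
           radius = model$features$radius[i]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pharmacophore model from JSON
#' @param path JSON path (schema of [write_pharmacophore()]).
#' @return A `pharmacophore_model`.
#' @export
read_pharmacophore <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  features <- dplyr::bind_rows(lapply(obj$features, function(f)
    tibble::tibble(kind = f$kind, x = f$center[[1]], y = f$center[[2]],
                   z = f$center[[3]],
                   radius = f$radius %||% unname(FEATURE_RADII[f$kind]))))
  pharmacophore_model(features, name = obj$name %||% "model",
                      required_count = obj$required_count %||% nrow(features))
}

# ---- matching ---------------------------------------------------------------

#' Match a ligand's features against a pharmacophore model
#'
#' Enumerates kind-compatible, injective correspondences between model
#' features and ligand features, pruned by pairwise-distance compatibility
#' (two model features can only map to ligand features whose separation
#' differs by at most the sum of the two tolerance radii). Each surviving
#' correspondence is scored by least-squares rigid alignment (if
#' `allow_alignment`) and accepted when every matched pair lies within the
#' model feature's radius; the correspondence minimizing the feature RMSD is
#' returned.
#'
#' @param model A `pharmacophore_model`.
#' @param ligand_features Feature tibble from [perceive_features()].
#' @param allow_alignment Optimize a rigid motion of the ligand features
#'   before checking tolerances (ligand-based screening); `FALSE` checks in
#'   the shared frame (receptor-aligned poses).
#' @param max_assignments Search cap; beyond it the result is flagged
#'   `inconclusive`.
#' @return A `match_result` (list with `matched`, `correspondence`,
#'   `feature_rmsd`, `transform`, `inconclusive`) or `NULL` when no
#'   correspondence satisfies the model.
#' @export
match_model <- function(model, ligand_features, allow_alignment = TRUE,
                        max_assignments = 1e5) {
  stopifnot(inherits(model, "pharmacophore_model"))
  lf <- tibble::as_tibble(ligand_features)
  nm <- nrow(model$features)
  if (nrow(lf) == 0L) return(NULL)
  mxyz <- as.matrix(model$features[, c("x", "y", "z")])
  lxyz <- as.matrix(lf[, c("x", "y", "z")])
  mrad <- model$features$radius
  # candidate ligand features per model feature (kind match)
  cand <- lapply(seq_len(nm), function(i) which(lf$kind == model$features$kind[i]))
  mdist <- as.matrix(stats::dist(mxyz))
  ldist <- as.matrix(stats::dist(lxyz))

  best <- NULL
  n_tried <- 0L
  inconclusive <- FALSE
  required <- model$required_count

  score_assignment <- function(assign) {
    sel <- which(!is.na(assign))
    if (length(sel) < required) return(NULL)
    mp <- mxyz[sel, , drop = FALSE]
    lp <- lxyz[assign[sel], , drop = FALSE]
    tr <- NULL
    if (allow_alignment && length(sel) >= 2) {
      tr <- .kabsch(mp, lp)
      lp <- .apply_transform(lp, tr)
    }
    dists <- sqrt(rowSums((mp - lp)^2))
    if (any(dists > mrad[sel] + 1e-9)) return(NULL)
    list(rmsd = sqrt(mean(dists^2)), assign = assign, transform = tr,
         n_matched = length(sel))
  }

  # depth-first over model features; NA = feature deliberately skipped
  recurse <- function(pos, assign, used, skipped) {
    if (n_tried > max_assignments) { inconclusive <<- TRUE; return() }
    if (pos > nm) {
      n_tried <<- n_tried + 1L
      res <- score_assignment(assign)
      if (!is.null(res) &&
          (is.null(best) ||
           res$n_matched > best$n_matched ||
           (res$n_matched == best$n_matched && res$rmsd < best$rmsd)))
        best <<- res
      return()
    }
    for (l in setdiff(cand[[pos]], assign[!is.na(assign)])) {
      # pairwise-distance pruning against already-assigned features
      ok <- TRUE
      for (p in seq_len(pos - 1L)) {
        if (is.na(assign[p])) next
        slack <- mrad[pos] + mrad[p]
        dm <- mdist[pos, p]; dl <- ldist[l, assign[p]]
        if (allow_alignment) {
          if (abs(dm - dl) > slack) { ok <- FALSE; break }
        } else {
          # shared frame: feature-to-target distances checked directly later;
          # still prune on absolute displacement
          if (sqrt(sum((mxyz[pos, ] - lxyz[l, ])^2)) > mrad[pos] + 1e-9) {
            ok <- FALSE; break
          }
        }
      }
      if (!allow_alignment &&
          sqrt(sum((mxyz[pos, ] - lxyz[l, ])^2)) > mrad[pos] + 1e-9) ok <- FALSE
      if (ok) {
        assign[pos] <- l
        recurse(pos + 1L, assign, used, skipped)
        assign[pos] <- NA_integer_
      }
    }
    if ((nm - pos) + sum(!is.na(assign)) >= required)
      recurse(pos + 1L, assign, used, skipped + 1L)
  }
  recurse(1L, rep(NA_integer_, nm), integer(0), 0L)

  if (is.null(best)) {
    if (inconclusive)
      return(structure(list(matched = FALSE, inconclusive = TRUE),
                       class = "match_result"))
    return(NULL)
  }
  structure(list(
    matched = TRUE,
    correspondence = best$assign,
    n_matched = best$n_matched,
    feature_rmsd = best$rmsd,
    transform = best$transform,
    inconclusive = inconclusive
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  if (isTRUE(x$matched))
    cat(sprintf("<match_result> %d feature(s) matched, RMSD = %.3f A\n",
                x$n_matched, x$feature_rmsd))
  else cat("<match_result> no match",
           if (isTRUE(x$inconclusive)) "(inconclusive: search cap reached)",
           "\n")
  invisible(x)
}

#' Rank pharmacophore hits by feature RMSD
#'
#' @param hits Tibble with columns `id` and `feature_rmsd`.
#' @return The tibble sorted by ascending RMSD, ties broken by `id`.
#' @export
rank_hits <- function(hits) {
  hits <- tibble::as_tibble(hits)
  if (!nrow(hits)) return(hits)
  stopifnot(all(c("id", "feature_rmsd") %in% names(hits)))
  dplyr::arrange(hits, .data$feature_rmsd, .data$id)
}

# ---- consensus model --------------------------------------------------------

#' Derive a consensus pharmacophore from aligned actives
#'
#' Greedy same-kind clustering of the pooled features of several aligned
#' active compounds (e.g. docked poses sharing a binding site frame):
#' features within `merge_radius` of a growing cluster centroid merge into
#' it; clusters supported by at least `min_support` of the actives become
#' model features at the cluster centroid with the kind's default radius.
#'
#' @param feature_sets List (length >= 2) of feature tibbles from
#'   [perceive_features()], all in one coordinate frame.
#' @param min_support Minimum fraction of actives contributing, in (0, 1].
#' @param merge_radius Clustering radius in Angstrom.
#' @param name Model name.
#' @return A `pharmacophore_model`; each feature carries a `support` column.
#' @export
consensus_features <- function(feature_sets, min_support = 0.5,
                               merge_radius = 1.0, name = "consensus") {
  stopifnot(is.list(feature_sets), length(feature_sets) >= 2,
            min_support > 0, min_support <= 1)
  pool <- dplyr::bind_rows(
    lapply(seq_along(feature_sets), function(k)
      dplyr::mutate(tibble::as_tibble(feature_sets[[k]])[, c("kind", "x", "y", "z")],
                    source = k)))
  n_src <- length(feature_sets)
  clusters <- list()
  for (r in seq_len(nrow(pool))) {
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      cl <- clusters[[ci]]
      if (cl$kind != pool$kind[r]) next
      cen <- colMeans(cl$xyz)
      if (sqrt(sum((cen - c(pool$x[r], pool$y[r], pool$z[r]))^2)) <= merge_radius) {
        cl$xyz <- rbind(cl$xyz, c(pool$x[r], pool$y[r], pool$z[r]))
        cl$sources <- c(cl$sources, pool$source[r])
        clusters[[ci]] <- cl
        placed <- TRUE
        break
      }
    }
    if (!placed)
      clusters[[length(clusters) + 1L]] <- list(
        kind = pool$kind[r],
        xyz = matrix(c(pool$x[r], pool$y[r], pool$z[r]), 1),
        sources = pool$source[r])
  }
  rows <- lapply(clusters, function(cl) {
    support <- length(unique(cl$sources)) / n_src
    if (support < min_support) return(NULL)
    cen <- colMeans(cl$xyz)
    tibble::tibble(kind = cl$kind, x = cen[1], y = cen[2], z = cen[3],
                   radius = unname(FEATURE_RADII[cl$kind]), support = support)
  })
  feats <- dplyr::bind_rows(rows)
  if (nrow(feats) < 2L)
    stop("Consensus yielded fewer than 2 supported features; lower ",
         "`min_support` or check the alignment", call. = FALSE)
  pharmacophore_model(feats, name = name)
}

# ---- steric filter ----------------------------------------------------------

#' Receptor steric (shape-tolerance) filter
#'
#' Rejects an aligned ligand pose when any heavy atom penetrates the
#' receptor's van der Waals envelope deeper than the tolerance allows: a
#' clash is a ligand atom closer to a receptor atom than
#' `max(0, vdW(receptor atom) - tolerance)`.
#'
#' @param mol A `mol_graph` pose in the receptor frame (or a matrix of
#'   ligand heavy-atom coordinates).
#' @param receptor_atoms Data frame with columns `element`, `x`, `y`, `z`.
#' @param tolerance Shape tolerance in Angstrom (default 1.5).
#' @return `TRUE` (accepted) or `FALSE` (steric clash), with attribute
#'   `n_clashes`.
#' @export
steric_filter <- function(mol, receptor_atoms, tolerance = 1.5) {
  stopifnot(tolerance >= 0)
  receptor_atoms <- tibble::as_tibble(receptor_atoms)
  if (!nrow(receptor_atoms))
    stop("Empty receptor atom list", call. = FALSE)
  stopifnot(all(c("element", "x", "y", "z") %in% names(receptor_atoms)))
  lig <- if (inherits(mol, "mol_graph")) mol_coords(mol) else as.matrix(mol)
  rad <- MOL_VDW_RADII[receptor_atoms$element]
  rad[is.na(rad)] <- 1.70
  thr <- pmax(0, rad - tolerance)
  rxyz <- as.matrix(receptor_atoms[, c("x", "y", "z")])
  n_clash <- 0L
  for (k in seq_len(nrow(lig))) {
    d <- sqrt(colSums((t(rxyz) - lig[k, ])^2))
    n_clash <- n_clash + sum(d < thr)
  }
  structure(n_clash == 0L, n_clashes = n_clash)
}
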