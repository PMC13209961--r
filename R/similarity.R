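# Fingerprints, Tanimoto similarity, the dual-threshold similarity gate, and
# similarity-driven target-hypothesis generation.
#
# Two schemes are supported, mirroring the two classical fingerprint families:
#  * "maccs"      -- the public 166 substructure keys, computed by OpenBabel
#  * "atom_pairs" -- Carhart-style topological atom pairs computed in-package:
#       atom type = (element, heavy-neighbor count, aromatic flag),
#       key = ordered (type_i, type_j) + shortest-path distance (capped at 30),
#       set semantics (presence only, no counts).
# Absolute bit patterns are implementation-defined for any fingerprint family;
# the encoding here is fixed and versioned so values are reproducible.

FP_SCHEMES <- c("atom_pairs", "maccs")
.AP_DIST_CAP <- 30L

new_fingerprint <- function(bits, scheme) {
  structure(list(scheme = scheme, bits = sort(unique(as.numeric(bits)))),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint> scheme=%s, %d on-bits\n", x$scheme, length(x$bits)))
  invisible(x)
}

# numeric atom-pair key; doubles carry these exactly (< 2^53)
.ap_atom_type <- function(mol) {
  elem_idx <- match(mol$atoms$element, names(MOL_ATOMIC_MASS))
  elem_idx[is.na(elem_idx)] <- length(MOL_ATOMIC_MASS) + 1L
  elem_idx * 16 + pmin(mol$atoms$degree, 7L) * 2 + as.integer(mol$atoms$aromatic)
}

.ap_bits <- function(mol) {
  n <- nrow(mol$atoms)
  if (n < 2) return(numeric(0))
  type <- .ap_atom_type(mol)
  d <- mol_distances(mol)
  keys <- numeric(0)
  pair <- which(upper.tri(d) & is.finite(d) & d > 0, arr.ind = TRUE)
  if (!nrow(pair)) return(numeric(0))
  t1 <- pmin(type[pair[, 1]], type[pair[, 2]])
  t2 <- pmax(type[pair[, 1]], type[pair[, 2]])
  dist <- pmin(d[pair], .AP_DIST_CAP)
  unique((t1 * 1024 + t2) * 64 + dist)
}

.maccs_bits <- function(mol) {
  if (nrow(mol$bonds) == 0L) {
    # OpenBabel's molfile round trip cannot carry bond-less species; the 166
    # keys are substructure patterns, so a single heavy atom gets no on-bits
    # beyond element counts -- return empty with that caveat documented.
    return(numeric(0))
  }
  sdf <- .mol_to_sdfset(mol)
  fp <- ChemmineR::fingerprintOB(sdf, "MACCS")
  bits <- which(methods::slot(fp[[1]], "fp") != 0)  # 1-based key numbers
  as.numeric(bits[bits <= 166])
}

.mol_to_sdfset <- function(mol) {
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  write_pose(mol, tmp)
  ChemmineR::read.SDFset(tmp)
}

#' Compute a molecular fingerprint
#'
#' @param mol A `mol_graph` (see [mol_from_smiles()]) or a compound-library
#'   tibble with a `mol` list-column.
#' @param scheme `"atom_pairs"` (topological Carhart pairs) or `"maccs"`
#'   (166 public substructure keys via OpenBabel).
#' @return For a single molecule, a `fingerprint`; for a library, a list of
#'   fingerprints named by compound id.
#' @details Equal canonical SMILES yield identical fingerprints. Molecules
#'   with fewer than two heavy atoms have an empty atom-pair fingerprint (no
#'   pair exists).
#' @export
compute_fingerprint <- function(mol, scheme = c("atom_pairs", "maccs")) {
  scheme <- match.arg(scheme)
  if (is.data.frame(mol)) {
    stopifnot("mol" %in% names(mol))
    fps <- lapply(mol$mol, compute_fingerprint, scheme = scheme)
    names(fps) <- mol$id
    return(fps)
  }
  stopifnot(inherits(mol, "mol_graph"))
  bits <- switch(scheme, atom_pairs = .ap_bits(mol), maccs = .maccs_bits(mol))
  new_fingerprint(bits, scheme)
}

#' Tanimoto similarity between two fingerprints
#'
#' The classic association coefficient for binary molecular features:
#' \deqn{T = c / (a + b - c)}
#' where `a` and `b` count the on-bits of each structure and `c` the shared
#' on-bits. Two empty fingerprints are defined to have similarity 0 (with a
#' warning): featureless structures should not appear spuriously similar.
#'
#' @param fp_a,fp_b `fingerprint` objects under the same scheme.
#' @return A `tanimoto_score`: list with `a`, `b`, `c` and `value`.
#' @export
tanimoto <- function(fp_a, fp_b) {
  stopifnot(inherits(fp_a, "fingerprint"), inherits(fp_b, "fingerprint"))
  if (!identical(fp_a$scheme, fp_b$scheme))
    stop("Fingerprint scheme mismatch: ", fp_a$scheme, " vs ", fp_b$scheme,
         call. = FALSE)
  a <- length(fp_a$bits); b <- length(fp_b$bits)
  c_ <- length(intersect(fp_a$bits, fp_b$bits))
  if (a + b == 0L) {
    warning("Both fingerprints are empty; Tanimoto defined as 0", call. = FALSE)
    value <- 0
  } else {
    value <- c_ / (a + b - c_)
  }
  structure(list(a = a, b = b, c = c_, value = value), class = "tanimoto_score")
}

#' @export
print.tanimoto_score <- function(x, ...) {
  cat(sprintf("<tanimoto> a=%d b=%d c=%d value=%.4f\n", x$a, x$b, x$c, x$value))
  invisible(x)
}

#' Dual-fingerprint similarity gate configuration
#'
#' The default thresholds correspond to a high overall-similarity criterion
#' expressed on the two fingerprint families jointly: atom-pair Tanimoto at
#' least 0.237 and substructure-key (MACCS) Tanimoto at least 0.528,
#' simultaneously.
#'
#' @param ap_min Atom-pair Tanimoto threshold.
#' @param maccs_min MACCS Tanimoto threshold.
#' @param inclusive Compare with `>=` (default) rather than `>`.
#' @return A `gate_config` list.
#' @export
gate_config <- function(ap_min = 0.237, maccs_min = 0.528, inclusive = TRUE) {
  stopifnot(ap_min >= 0, ap_min <= 1, maccs_min >= 0, maccs_min <= 1,
            is.logical(inclusive))
  structure(list(ap_min = ap_min, maccs_min = maccs_min, inclusive = inclusive),
            class = "gate_config")
}

#' Apply the dual-threshold similarity gate
#'
#' @param tani_ap,tani_maccs Numeric vectors of Tanimoto values in \[0, 1\].
#' @param config A [gate_config()].
#' @return Logical vector: `TRUE` where both thresholds are met.
#' @export
similarity_gate <- function(tani_ap, tani_maccs, config = gate_config()) {
  stopifnot(all(tani_ap >= 0 & tani_ap <= 1, na.rm = TRUE),
            all(tani_maccs >= 0 & tani_maccs <= 1, na.rm = TRUE))
  if (config$inclusive)
    tani_ap >= config$ap_min & tani_maccs >= config$maccs_min
  else
    tani_ap > config$ap_min & tani_maccs > config$maccs_min
}

#' Propose biological targets by similarity to reference drugs
#'
#' For every (query compound, reference drug) pair passing the dual-fingerprint
#' gate, emits a target hypothesis carrying the drug's known targets --
#' structurally comparable molecules often share bioactivity, so a strong
#' dual-fingerprint match to an approved kinase inhibitor nominates that
#' inhibitor's kinases for the query compound.
#'
#' @param query_library,drug_library Compound-library tibbles
#'   (see [compound_library()]).
#' @param drug_target_map Data frame with columns `drug_id`, `target_id`;
#'   every drug in `drug_library` must appear.
#' @param config A [gate_config()].
#' @return A tibble with one row per passing pair: `compound_id`, `drug_id`,
#'   `tani_ap`, `tani_maccs`, and a `proposed_targets` list-column; sorted by
#'   descending `tani_ap`, then `tani_maccs`, then `drug_id`.
#' @export
propose_targets <- function(query_library, drug_library, drug_target_map,
                            config = gate_config()) {
  stopifnot(all(c("drug_id", "target_id") %in% names(drug_target_map)))
  unmapped <- setdiff(drug_library$id, drug_target_map$drug_id)
  if (length(unmapped))
    stop("Drug(s) missing from drug_target_map: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  if (nrow(query_library) == 0L || nrow(drug_library) == 0L) {
    return(tibble::tibble(compound_id = character(), drug_id = character(),
                          tani_ap = numeric(), tani_maccs = numeric(),
                          proposed_targets = list()))
  }
  fq_ap <- compute_fingerprint(query_library, "atom_pairs")
  fq_mc <- compute_fingerprint(query_library, "maccs")
  fd_ap <- compute_fingerprint(drug_library, "atom_pairs")
  fd_mc <- compute_fingerprint(drug_library, "maccs")
  targets_of <- split(as.character(drug_target_map$target_id),
                      as.character(drug_target_map$drug_id))

  grid <- tidyr::expand_grid(compound_id = query_library$id,
                             drug_id = drug_library$id)
  sim <- purrr::pmap(grid, function(compound_id, drug_id) {
    s_ap <- suppressWarnings(tanimoto(fq_ap[[compound_id]], fd_ap[[drug_id]]))
    s_mc <- suppressWarnings(tanimoto(fq_mc[[compound_id]], fd_mc[[drug_id]]))
    c(tani_ap = s_ap$value, tani_maccs = s_mc$value)
  })
  grid$tani_ap <- vapply(sim, `[[`, numeric(1), "tani_ap")
  grid$tani_maccs <- vapply(sim, `[[`, numeric(1), "tani_maccs")
  hits <- grid[similarity_gate(grid$tani_ap, grid$tani_maccs, config), ,
               drop = FALSE]
  hits$proposed_targets <- lapply(hits$drug_id,
                                  function(d) sort(unique(targets_of[[d]])))
  dplyr::arrange(hits, dplyr::desc(.data$tani_ap), dplyr::desc(.data$tani_maccs),
                 .data$drug_id)
}
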