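# Readers/writers for the formats the pipeline touches: SMILES libraries,
# docking score tables (CSV), and ligand poses (SDF V2000 / PDB HETATM).

SCORE_COLUMNS <- c("ligand_id", "target_id", "affinity",
                   "cnn_pose_score", "cnn_affinity")

#' Read a SMILES compound library
#'
#' One compound per line: a SMILES string, whitespace, then an identifier.
#' Every line must parse; SMILES are canonicalized on read so identical
#' structures compare equal downstream.
#'
#' @param path Path to the library file.
#' @return A tibble with columns `id`, `smiles` (canonical) and a `mol`
#'   list-column of molecular graphs.
#' @export
read_smiles_library <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- .normalize_minus(lines)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) {
    return(tibble::tibble(id = character(), smiles = character(), mol = list()))
  }
  lineno <- which(keep)
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  bad_shape <- lengths(parts) < 2
  if (any(bad_shape))
    stop("Missing identifier on line(s): ",
         paste(lineno[bad_shape], collapse = ", "), call. = FALSE)
  smiles <- vapply(parts, `[[`, character(1), 1)
  id <- vapply(parts, `[[`, character(1), 2)
  if (anyDuplicated(id))
    stop("Duplicate compound id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  can <- canonicalize_smiles(smiles, strict = FALSE)
  if (any(!nzchar(can)))
    stop("Unparsable SMILES on line(s): ",
         paste(lineno[!nzchar(can)], collapse = ", "), call. = FALSE)
  compound_library(smiles = smiles, id = id)
}

#' Build a compound library from SMILES vectors
#'
#' @param smiles Character vector of SMILES.
#' @param id Character vector of unique identifiers.
#' @return A tibble with `id`, canonical `smiles`, and `mol` list-column.
#' @export
compound_library <- function(smiles, id = NULL) {
  if (is.null(id)) id <- paste0("cpd", seq_along(smiles))
  stopifnot(length(id) == length(smiles), !anyDuplicated(id), all(nzchar(id)))
  mols <- mol_from_smiles(smiles, id)
  tibble::tibble(
    id = id,
    smiles = canonicalize_smiles(smiles),
    mol = unname(mols)
  )
}

# validate one score tibble against the DockingRecord invariants
.validate_scores <- function(df, context = "score table") {
  missing <- setdiff(SCORE_COLUMNS, names(df))
  if (length(missing))
    stop(context, " is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- tibble::as_tibble(df)
  df$ligand_id <- as.character(df$ligand_id)
  df$target_id <- as.character(df$target_id)
  for (col in c("affinity", "cnn_pose_score", "cnn_affinity")) {
    if (is.character(df[[col]]))
      df[[col]] <- as.numeric(.normalize_minus(df[[col]]))
    else df[[col]] <- as.numeric(df[[col]])
  }
  bad <- which(!is.finite(df$affinity))
  if (length(bad))
    stop(context, ": non-finite affinity in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(df$cnn_pose_score) |
                 df$cnn_pose_score < 0 | df$cnn_pose_score > 1)
  if (length(bad))
    stop(context, ": cnn_pose_score outside [0, 1] in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(df$cnn_affinity) | df$cnn_affinity <= 0)
  if (length(bad))
    stop(context, ": cnn_affinity must be positive in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  key <- paste(df$ligand_id, df$target_id, sep = "\r")
  if (anyDuplicated(key))
    stop(context, ": duplicate (ligand_id, target_id) pair(s): ",
         paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = ", "),
         call. = FALSE)
  df
}

#' Validate a docking score table
#'
#' Checks and coerces a data frame of per-ligand docking results to the
#' canonical schema: columns `ligand_id`, `target_id`, `affinity` (kcal/mol,
#' negative is stronger), `cnn_pose_score` (in \[0, 1\]) and `cnn_affinity`
#' (positive, unitless). `(ligand_id, target_id)` pairs must be unique.
#'
#' @param df A data frame.
#' @return A validated tibble (extra columns are preserved).
#' @export
score_table <- function(df) {
  .validate_scores(df)
}

#' Read a docking score table from CSV
#'
#' The CSV must carry a header with at least the canonical score columns.
#' Unicode minus signs (as found in typeset tables) are normalized to ASCII.
#'
#' @param path CSV file path.
#' @return A validated score tibble.
#' @export
read_score_table <- function(path) {
  stopifnot(file.exists(path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        locale = readr::locale(encoding = "UTF-8"))
  .validate_scores(df, context = basename(path))
}

#' Write a docking score table to CSV
#'
#' @param scores A score tibble (validated on write).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  scores <- .validate_scores(scores)
  readr::write_csv(scores, path)
  invisible(path)
}

# ---- poses ------------------------------------------------------------------

#' Read a ligand pose (SDF V2000 or PDB HETATM)
#'
#' Reads one ligand conformer with heavy-atom coordinates. SDF input also
#' populates the bond table; for PDB input only HETATM records are used and
#' bonds are inferred from interatomic distances (covalent-radius rule), since
#' PDB ligand records carry no bond orders. Hydrogens are dropped.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"sdf"` or `"pdb"`.
#' @param index For multi-molecule SDF files, which record to read; reading a
#'   multi-molecule file without `index` is an error.
#' @return A `mol_graph` with conformer coordinates.
#' @export
read_pose <- function(path, format = c("auto", "sdf", "pdb"), index = NULL) {
  stopifnot(file.exists(path))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sdf = "sdf", mol = "sdf", pdb = "pdb",
                     stop("Cannot infer pose format from extension: ", ext,
                          call. = FALSE))
  }
  if (format == "sdf") {
    blocks <- .sdf_split_blocks(readLines(path, warn = FALSE))
    if (!length(blocks)) stop("No molecules found in ", path, call. = FALSE)
    if (length(blocks) > 1 && is.null(index))
      stop(path, " contains ", length(blocks),
           " molecules; pass `index` to select one", call. = FALSE)
    if (is.null(index)) index <- 1L
    stopifnot(index >= 1, index <= length(blocks))
    .sdf_parse_block(blocks[[index]])
  } else {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    het <- pdb$atom[pdb$atom$type == "HETATM", , drop = FALSE]
    if (!nrow(het))
      stop("No HETATM records in ", path,
           " (protein ATOM records are not ligand poses)", call. = FALSE)
    elem <- het$elesy
    if (any(is.na(elem) | !nzchar(elem)))
      elem <- toupper(substr(trimws(het$elety), 1, 1))
    elem <- paste0(substr(elem, 1, 1), tolower(substr(elem, 2, 2)))
    keep <- !(elem %in% c("H", "D"))
    atoms <- tibble::tibble(
      idx = seq_len(sum(keep)),
      element = elem[keep],
      x = het$x[keep], y = het$y[keep], z = het$z[keep],
      charge = 0, n_h_explicit = 0L
    )
    bonds <- .infer_bonds(atoms)
    new_mol_graph(atoms, bonds, name = basename(path))
  }
}

# distance-based bond perception for PDB ligands: bonded when closer than
# 1.25 x sum of covalent radii (all treated as single bonds)
.infer_bonds <- function(atoms) {
  cov <- c(C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07, F = 0.57,
           Cl = 1.02, Br = 1.20, I = 1.39, B = 0.84, Si = 1.11)
  n <- nrow(atoms)
  if (n < 2) return(tibble::tibble(i = integer(), j = integer(), order = integer()))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- cov[atoms$element]; r[is.na(r)] <- 0.9
  out <- list()
  for (i in seq_len(n - 1)) {
    d <- sqrt(colSums((t(xyz[(i + 1):n, , drop = FALSE]) - xyz[i, ])^2))
    hit <- which(d < 1.25 * (r[i] + r[(i + 1):n]) & d > 0.4)
    if (length(hit))
      out[[length(out) + 1L]] <- tibble::tibble(i = i, j = i + hit, order = 1L)
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(i = integer(), j = integer(), order = integer())
}

#' Write a ligand pose as SDF V2000
#'
#' Coordinates are written at the molfile field precision (1e-4 Angstrom), so
#' a write-then-read round trip reproduces them well within 1e-3 Angstrom.
#'
#' @param mol A `mol_graph` with conformer coordinates.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pose <- function(mol, path) {
  stopifnot(inherits(mol, "mol_graph"))
  n_a <- nrow(mol$atoms); n_b <- nrow(mol$bonds)
  header <- c(mol$name, "  kinscreen", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n_a, n_b)
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        mol$atoms$x, mol$atoms$y, mol$atoms$z, mol$atoms$element)
  bond_lines <- if (n_b) sprintf("%3d%3d%3d  0  0  0  0",
                                 mol$bonds$i, mol$bonds$j, mol$bonds$order)
    else character(0)
  chg <- which(mol$atoms$charge != 0)
  chg_lines <- if (length(chg))
    paste0("M  CHG", sprintf("%3d", length(chg)),
           paste0(sprintf("%4d%4d", chg, mol$atoms$charge[chg]), collapse = ""))
    else character(0)
  writeLines(c(header, counts, atom_lines, bond_lines, chg_lines,
               "M  END", "$$$$"), path)
  invisible(path)
}
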