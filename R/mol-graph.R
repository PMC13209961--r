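# Internal heavy-atom molecular graph built from SDF V2000 text.
#
# Everything downstream (fingerprints, feature perception, RMSD, properties)
# consumes this one representation. Hydrogens are dropped on construction and
# folded into a per-atom hydrogen count; coordinates are Angstrom.

MOL_DEFAULT_VALENCE <- c(
  B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1, Se = 2, As = 3
)

# average atomic masses for MW checks/fallbacks (monoisotopic not needed)
MOL_ATOMIC_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.086, P = 30.974, S = 32.065, Cl = 35.453, Br = 79.904, I = 126.904,
  Se = 78.971, As = 74.922
)

# Bondi van der Waals radii (Angstrom); used by the receptor steric filter.
MOL_VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80, S = 1.80,
  Cl = 1.75, Br = 1.85, I = 1.98, B = 1.92, Si = 2.10, Se = 1.90, As = 1.85
)

# SDF atom-block charge codes (field 4): 1..7 -> +3..-3, 0/4 -> neutral
.sdf_charge_code <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0,
                      `5` = -1, `6` = -2, `7` = -3)

new_mol_graph <- function(atoms, bonds, name = "", source_sdf = NULL) {
  stopifnot(is.data.frame(atoms), is.data.frame(bonds))
  mol <- structure(
    list(atoms = atoms, bonds = bonds, name = name, source_sdf = source_sdf),
    class = "mol_graph"
  )
  .mol_annotate(mol)
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %s: %d heavy atoms, %d bonds, %d ring(s)\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              nrow(x$atoms), nrow(x$bonds), mol_n_rings(x)))
  invisible(x)
}

#' @export
format.mol_graph <- function(x, ...) {
  sprintf("<mol_graph %s: %d atoms>", x$name, nrow(x$atoms))
}

# ---- SDF V2000 text parsing -------------------------------------------------

# Split raw SDF text into per-molecule blocks on "$$$$".
.sdf_split_blocks <- function(lines) {
  lines <- sub("\r$", "", lines)
  ends <- which(trimws(lines) == "$$$$")
  if (length(ends) == 0L) {
    if (all(!nzchar(trimws(lines)))) return(list())
    return(list(lines))
  }
  starts <- c(1L, head(ends, -1L) + 1L)
  blocks <- Map(function(s, e) lines[s:(e - 1L)], starts, ends)
  blocks[vapply(blocks, function(b) any(nzchar(trimws(b))), logical(1))]
}

# Parse one molfile block into a mol_graph. Drops hydrogens, applies M CHG.
.sdf_parse_block <- function(block, drop_h = TRUE) {
  if (length(block) < 4L)
    stop("SDF block too short to contain a counts line", call. = FALSE)
  name <- trimws(block[1])
  counts <- block[4]
  if (grepl("V3000", counts, fixed = TRUE))
    stop("SDF V3000 is not supported; please provide V2000 molfiles",
         call. = FALSE)
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n_atoms) || is.na(n_bonds))
    stop("Malformed SDF counts line: ", sQuote(counts), call. = FALSE)
  if (length(block) < 4L + n_atoms + n_bonds)
    stop("SDF block truncated: counts line declares more atoms/bonds than present",
         call. = FALSE)

  atom_lines <- block[seq_len(n_atoms) + 4L]
  fields <- strsplit(trimws(.normalize_minus(atom_lines)), "\\s+")
  atoms <- tibble::tibble(
    element = vapply(fields, function(f) f[4], character(1)),
    x = vapply(fields, function(f) as.numeric(f[1]), numeric(1)),
    y = vapply(fields, function(f) as.numeric(f[2]), numeric(1)),
    z = vapply(fields, function(f) as.numeric(f[3]), numeric(1)),
    charge_code = vapply(fields, function(f)
      if (length(f) >= 6) suppressWarnings(as.integer(f[6])) else 0L, integer(1))
  )
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z) ||
      any(!is.finite(atoms$x + atoms$y + atoms$z)))
    stop("Non-finite or unparsable coordinates in SDF atom block", call. = FALSE)
  atoms$charge_code[is.na(atoms$charge_code)] <- 0L
  atoms$charge <- unname(.sdf_charge_code[as.character(pmin(pmax(atoms$charge_code, 0L), 7L))])

  if (n_bonds > 0L) {
    bond_lines <- block[4L + n_atoms + seq_len(n_bonds)]
    bonds <- tibble::tibble(
      i = as.integer(substr(bond_lines, 1, 3)),
      j = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9))
    )
    if (anyNA(bonds$i) || anyNA(bonds$j) || anyNA(bonds$order) ||
        any(bonds$i < 1L | bonds$i > n_atoms | bonds$j < 1L | bonds$j > n_atoms))
      stop("SDF bond block references invalid atom indices", call. = FALSE)
  } else {
    bonds <- tibble::tibble(i = integer(), j = integer(), order = integer())
  }

  # "M  CHG" property lines override every atom-block charge code
  chg_lines <- grep("^M  CHG", block, value = TRUE)
  if (length(chg_lines)) {
    atoms$charge <- 0
    for (cl in chg_lines) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG\\s+\\d+", "", cl)), "\\s+")[[1]])
      if (length(f) >= 2)
        for (k in seq(1, length(f) - 1, by = 2)) atoms$charge[f[k]] <- f[k + 1]
    }
  }

  if (drop_h) {
    hmask <- atoms$element %in% c("H", "D", "T")
    keep <- which(!hmask)
    remap <- integer(n_atoms); remap[keep] <- seq_along(keep)
    n_h_explicit <- integer(length(keep))
    if (nrow(bonds)) {
      h_i <- hmask[bonds$i]; h_j <- hmask[bonds$j]
      for (r in which(xor(h_i, h_j))) {
        heavy <- if (h_i[r]) bonds$j[r] else bonds$i[r]
        n_h_explicit[remap[heavy]] <- n_h_explicit[remap[heavy]] + 1L
      }
      bonds <- bonds[!h_i & !h_j, , drop = FALSE]
      bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
    }
    atoms <- atoms[keep, , drop = FALSE]
    atoms$n_h_explicit <- n_h_explicit
  } else {
    atoms$n_h_explicit <- 0L
  }
  atoms$charge_code <- NULL
  atoms$idx <- seq_len(nrow(atoms))
  atoms <- atoms[c("idx", "element", "x", "y", "z", "charge", "n_h_explicit")]
  new_mol_graph(atoms, tibble::as_tibble(bonds), name = name, source_sdf = block)
}

# ---- derived annotations ----------------------------------------------------

.mol_igraph <- function(mol) {
  igraph::graph_from_data_frame(
    d = if (nrow(mol$bonds)) mol$bonds[, c("i", "j")] else
      data.frame(i = integer(), j = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(mol$atoms)))
  )
}

# Smallest ring through each edge; returned as unique sorted index vectors.
.mol_rings <- function(mol, max_size = 8L) {
  if (nrow(mol$bonds) == 0L || nrow(mol$atoms) < 3L) return(list())
  g <- .mol_igraph(mol)
  rings <- list()
  for (r in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[r]; j <- mol$bonds$j[r]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = as.character(i),
                                                  to = as.character(j))$vpath[[1]])
    if (length(sp) >= 2 && length(sp) <= max_size) {
      ring <- sort(as.integer(igraph::V(g2)$name[as.integer(sp)]))
      rings[[paste(ring, collapse = "-")]] <- ring
    }
  }
  unname(rings)
}

# Kekule-pattern aromaticity: a 6-ring whose internal double bonds form a
# perfect matching, or a 5-ring with two internal doubles and a lone-pair
# heteroatom (N/O/S) on the uncovered position. A deliberate simplification
# of Hueckel perception; adequate for kekulized drug-like input.
.mol_aromatic <- function(mol, rings) {
  n <- nrow(mol$atoms)
  arom_atom <- logical(n)
  arom_bond <- logical(nrow(mol$bonds))
  if (!length(rings)) return(list(atom = arom_atom, bond = arom_bond))
  bkey <- paste(pmin(mol$bonds$i, mol$bonds$j), pmax(mol$bonds$i, mol$bonds$j))
  for (ring in rings) {
    sz <- length(ring)
    if (!sz %in% c(5L, 6L)) next
    if (!all(mol$atoms$element[ring] %in% c("C", "N", "O", "S"))) next
    in_ring <- mol$bonds$i %in% ring & mol$bonds$j %in% ring
    ring_doubles <- which(in_ring & (mol$bonds$order == 2L | mol$bonds$order == 4L))
    # order 4 (aromatic-typed input) on every ring bond also qualifies
    if (all(mol$bonds$order[in_ring] == 4L) && sum(in_ring) == sz) {
      aromatic <- TRUE
    } else {
      covered <- c(mol$bonds$i[ring_doubles], mol$bonds$j[ring_doubles])
      if (anyDuplicated(covered)) next
      covered <- intersect(covered, ring)
      aromatic <-
        (sz == 6L && length(ring_doubles) == 3L && length(covered) == 6L) ||
        (sz == 5L && length(ring_doubles) == 2L && length(covered) == 4L &&
           mol$atoms$element[setdiff(ring, covered)] %in% c("N", "O", "S"))
    }
    if (isTRUE(aromatic)) {
      arom_atom[ring] <- TRUE
      arom_bond[in_ring] <- TRUE
    }
  }
  list(atom = arom_atom, bond = arom_bond)
}

# Effective valence = default + formal charge (covers N+, O-, etc.)
.mol_implicit_h <- function(mol) {
  n <- nrow(mol$atoms)
  order_sum <- numeric(n)
  if (nrow(mol$bonds)) {
    eff <- ifelse(mol$bonds$order == 4L, 1.5, mol$bonds$order)
    for (r in seq_len(nrow(mol$bonds))) {
      order_sum[mol$bonds$i[r]] <- order_sum[mol$bonds$i[r]] + eff[r]
      order_sum[mol$bonds$j[r]] <- order_sum[mol$bonds$j[r]] + eff[r]
    }
  }
  val <- MOL_DEFAULT_VALENCE[mol$atoms$element]
  val[is.na(val)] <- 0
  eff_val <- unname(val) + mol$atoms$charge
  pmax(0L, as.integer(floor(eff_val - order_sum - mol$atoms$n_h_explicit))) +
    mol$atoms$n_h_explicit
}

.mol_annotate <- function(mol) {
  rings <- .mol_rings(mol)
  arom <- .mol_aromatic(mol, rings)
  mol$rings <- rings
  mol$atoms$aromatic <- arom$atom
  if (nrow(mol$bonds)) mol$bonds$aromatic <- arom$bond else
    mol$bonds$aromatic <- logical(0)
  mol$atoms$n_h <- .mol_implicit_h(mol)
  deg <- integer(nrow(mol$atoms))
  if (nrow(mol$bonds)) {
    tab <- table(factor(c(mol$bonds$i, mol$bonds$j), levels = seq_len(nrow(mol$atoms))))
    deg <- as.integer(tab)
  }
  mol$atoms$degree <- deg
  mol
}

mol_n_rings <- function(mol) {
  # cyclomatic number = SSSR ring count for a connected-component union
  comps <- if (nrow(mol$bonds)) {
    igraph::components(.mol_igraph(mol))$no
  } else nrow(mol$atoms)
  nrow(mol$bonds) - nrow(mol$atoms) + comps
}

mol_coords <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

# topological shortest-path distances between heavy atoms (hops)
mol_distances <- function(mol) {
  if (nrow(mol$atoms) == 0) return(matrix(numeric(0), 0, 0))
  igraph::distances(.mol_igraph(mol))
}

# ---- constructors -----------------------------------------------------------

.normalize_minus <- function(x) gsub("−", "-", x)

#' Build molecular graphs from SMILES strings
#'
#' Converts SMILES to 2D structures with OpenBabel (via \pkg{ChemmineOB}) and
#' parses the result into the package's internal heavy-atom graph
#' representation. Hydrogens are implicit.
#'
#' @param smiles Character vector of SMILES strings.
#' @param id Optional character vector of identifiers (same length).
#' @return A list of `mol_graph` objects.
#' @examples
#' mol <- mol_from_smiles("c1ccccc1", "benzene")[[1]]
#' mol
#' @export
mol_from_smiles <- function(smiles, id = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  if (is.null(id)) id <- paste0("mol", seq_along(smiles))
  stopifnot(length(id) == length(smiles))
  bad <- !nzchar(canonicalize_smiles(smiles, strict = FALSE))
  if (any(bad))
    stop("Unparsable SMILES: ",
         paste(sprintf("%s (%s)", smiles[bad], id[bad]), collapse = ", "),
         call. = FALSE)
  src <- paste0(smiles, " ", id, "\n", collapse = "")
  sdf_text <- ChemmineOB::convertFormat(
    "SMI", "SDF", source = src,
    options = data.frame(names = "gen2D", args = "")
  )
  blocks <- .sdf_split_blocks(strsplit(sdf_text, "\n", fixed = TRUE)[[1]])
  if (length(blocks) != length(smiles))
    stop("Structure conversion dropped ", length(smiles) - length(blocks),
         " molecule(s)", call. = FALSE)
  out <- lapply(seq_along(blocks), function(k) {
    mol <- .sdf_parse_block(blocks[[k]])
    mol$name <- id[k]
    mol
  })
  names(out) <- id
  out
}

#' Canonicalize SMILES strings
#'
#' Uses OpenBabel's canonical SMILES writer, so two spellings of the same
#' structure map to one string. Unparsable input yields `""` (or an error when
#' `strict = TRUE`).
#'
#' @param smiles Character vector.
#' @param strict Error on unparsable input instead of returning `""`.
#' @return Character vector of canonical SMILES.
#' @export
canonicalize_smiles <- function(smiles, strict = TRUE) {
  stopifnot(is.character(smiles))
  if (!length(smiles)) return(character(0))
  src <- paste0(smiles, " m", seq_along(smiles), "\n", collapse = "")
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", source = src),
    error = function(e) ""
  )
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  got <- vapply(parts, function(p) if (length(p) >= 1) p[1] else "", character(1))
  tags <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", character(1))
  res <- character(length(smiles))
  hit <- match(paste0("m", seq_along(smiles)), tags)
  res[!is.na(hit)] <- got[hit[!is.na(hit)]]
  if (strict && any(!nzchar(res)))
    stop("Unparsable SMILES: ",
         paste(sQuote(smiles[!nzchar(res)]), collapse = ", "), call. = FALSE)
  res
}
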