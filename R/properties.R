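# Drug-likeness properties and the inclusive window filter.
#
# Conventions: MW, TPSA (Ertl fragment method) and logP (atomic-contribution)
# come from OpenBabel; hydrogen-bond acceptor/donor counts reuse the same
# perception rules as the HAC/HDO pharmacophore features; rotatable bonds are
# non-ring single bonds between non-terminal heavy atoms; ring count is the
# smallest-set-of-smallest-rings size (cyclomatic number).

#' Compute drug-likeness properties
#'
#' @param x A `mol_graph` or a compound-library tibble with a `mol`
#'   list-column.
#' @return A tibble with one row per molecule: `id`, `mw` (Da), `tpsa`
#'   (Angstrom^2), `logp`, `n_rotatable`, `n_hba`, `n_hbd`, `n_rings`.
#' @export
compute_properties <- function(x) {
  mols <- if (is.data.frame(x)) x$mol else list(x)
  ids <- if (is.data.frame(x)) x$id else
    vapply(mols, function(m) m$name, character(1))
  stopifnot(all(vapply(mols, inherits, logical(1), "mol_graph")))

  ob <- .propOB_many(mols)
  rows <- lapply(seq_along(mols), function(k) {
    mol <- mols[[k]]
    feats <- perceive_features(mol)
    tibble::tibble(
      id = ids[k],
      mw = ob$MW[k],
      tpsa = ob$TPSA[k],
      logp = ob$logP[k],
      n_rotatable = .n_rotatable(mol),
      n_hba = sum(feats$kind == "HAC"),
      n_hbd = sum(feats$kind == "HDO"),
      n_rings = mol_n_rings(mol)
    )
  })
  dplyr::bind_rows(rows)
}

.propOB_many <- function(mols) {
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  con <- file(tmp, "w")
  for (m in mols) {
    n_a <- nrow(m$atoms); n_b <- nrow(m$bonds)
    writeLines(c(m$name, "  kinscreen", "",
                 sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n_a, n_b),
                 sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         m$atoms$x, m$atoms$y, m$atoms$z, m$atoms$element),
                 if (n_b) sprintf("%3d%3d%3d  0  0  0  0",
                                  m$bonds$i, m$bonds$j, m$bonds$order),
                 "M  END", "$$$$"), con)
  }
  close(con)
  sdf <- ChemmineR::read.SDFset(tmp)
  p <- ChemmineR::propOB(sdf)
  if (nrow(p) != length(mols))
    stop("Property computation failed for ", length(mols) - nrow(p),
         " molecule(s)", call. = FALSE)
  p
}

.n_rotatable <- function(mol) {
  if (nrow(mol$bonds) == 0L) return(0L)
  ring_bond <- logical(nrow(mol$bonds))
  for (ring in mol$rings)
    ring_bond <- ring_bond |
      (mol$bonds$i %in% ring & mol$bonds$j %in% ring)
  deg <- mol$atoms$degree
  sum(mol$bonds$order == 1L & !ring_bond &
        deg[mol$bonds$i] > 1L & deg[mol$bonds$j] > 1L)
}

#' Drug-likeness property window
#'
#' Inclusive per-property intervals; the defaults delimit the property space
#' of the FDA-approved kinase-inhibitor reference set used throughout the
#' pipeline (molecular weight in Da, TPSA in Angstrom^2, Crippen-type logP,
#' rotatable bonds, H-bond acceptors/donors, ring count).
#'
#' @param mw,tpsa,logp,n_rotatable,n_hba,n_hbd,n_rings Length-2 numeric
#'   `c(lower, upper)` vectors.
#' @return A `property_window` list.
#' @export
property_window <- function(mw = c(416.81, 461.47),
                            tpsa = c(83.48, 95.83),
                            logp = c(2.62, 3.49),
                            n_rotatable = c(5, 7),
                            n_hba = c(4, 10),
                            n_hbd = c(0, 5),
                            n_rings = c(4, 5)) {
  w <- list(mw = mw, tpsa = tpsa, logp = logp, n_rotatable = n_rotatable,
            n_hba = n_hba, n_hbd = n_hbd, n_rings = n_rings)
  for (nm in names(w)) {
    stopifnot(length(w[[nm]]) == 2L)
    if (w[[nm]][1] > w[[nm]][2])
      stop("Window lower bound exceeds upper bound for ", nm, call. = FALSE)
  }
  structure(w, class = "property_window")
}

#' Filter compounds by drug-likeness windows
#'
#' A compound passes when every property lies inside its inclusive window.
#'
#' @param x A `mol_graph`, compound-library tibble, or a properties tibble
#'   from [compute_properties()].
#' @param window A [property_window()].
#' @return The properties tibble with one logical verdict column per property
#'   (`mw_ok`, `tpsa_ok`, ...) and an overall `pass` column.
#' @export
property_filter <- function(x, window = property_window()) {
  stopifnot(inherits(window, "property_window"))
  props <- if (is.data.frame(x) && all(c("mw", "tpsa") %in% names(x)))
    tibble::as_tibble(x) else compute_properties(x)
  pass <- rep(TRUE, nrow(props))
  for (nm in names(unclass(window))) {
    v <- props[[nm]]
    if (is.null(v) || anyNA(v))
      stop("Property ", nm, " could not be computed", call. = FALSE)
    ok <- v >= window[[nm]][1] & v <= window[[nm]][2]
    props[[paste0(nm, "_ok")]] <- ok
    pass <- pass & ok
  }
  props$pass <- pass
  props
}
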