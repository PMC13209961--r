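# Shared fixture builders. Everything is generated in code; the only files
# read are the CSV tables shipped under inst/extdata.

extdata <- function(name) {
  path <- system.file("extdata", name, package = "kinscreen")
  if (!nzchar(path)) stop("missing extdata fixture: ", name)
  path
}

fda_benchmark <- function() read_score_table(extdata("fda_kinase_benchmark.csv"))

# the published threshold values, as users would enter them
published_thresholds <- function() {
  threshold_set(-9.00, 0.843, 7.702, -6.82, 0.526, 7.010)
}

# hand-buildable fingerprint (bypasses molecule parsing)
raw_fp <- function(bits, scheme = "atom_pairs") {
  structure(list(scheme = scheme, bits = sort(unique(as.numeric(bits)))),
            class = "fingerprint")
}

# a rigid 3D toy molecule written as SDF text: 3-atom bent chain O-C-N
toy_sdf_lines <- function(name = "toy3") {
  c(name, "  test", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.4000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.1000    1.2000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "  2  3  1  0  0  0  0",
    "M  END", "$$$$")
}

write_toy_sdf <- function(path, name = "toy3") {
  writeLines(toy_sdf_lines(name), path)
  path
}

# apply a random rigid motion (proper rotation + translation) to a mol_graph
random_rigid_motion <- function(mol, seed = 1) {
  set.seed(seed)
  th <- stats::runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0),
              c(0, 0, 1))
  R <- Rx %*% Ry %*% Rz
  tr <- stats::runif(3, -5, 5)
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")]) %*% t(R)
  mol$atoms$x <- xyz[, 1] + tr[1]
  mol$atoms$y <- xyz[, 2] + tr[2]
  mol$atoms$z <- xyz[, 3] + tr[3]
  mol
}

# a benzene with distinct per-atom z jitter so automorphisms are non-trivial
jittered_benzene <- function(seed = 1) {
  mol <- mol_from_smiles("c1ccccc1", "benz")[[1]]
  set.seed(seed)
  mol$atoms$z <- stats::rnorm(6, 0, 0.05)
  mol
}
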