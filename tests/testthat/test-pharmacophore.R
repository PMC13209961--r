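# Feature perception, model matching, drug-likeness windows, steric filter.

test_that("feature perception follows the shipped rules", {
  benz <- mol_from_smiles("c1ccccc1", "benz")[[1]]
  f <- perceive_features(benz)
  expect_equal(f$kind, "ARO")
  expect_equal(f$radius, 1.1)
  # centroid of the ring
  expect_equal(f$x, mean(benz$atoms$x))

  meth <- mol_from_smiles("C", "meth")[[1]]
  expect_equal(nrow(perceive_features(meth)), 0L)

  pyr <- mol_from_smiles("c1ccncc1", "pyr")[[1]]
  f <- perceive_features(pyr)
  expect_setequal(f$kind, c("ARO", "HAC"))
  expect_equal(sum(f$kind == "HAC"), 1L)  # ring N accepts

  # pyrrole N-H: donor but not acceptor (aromatic N-H rule)
  pyrl <- perceive_features(mol_from_smiles("c1cc[nH]c1", "pyrl")[[1]])
  expect_true("HDO" %in% pyrl$kind)
  expect_false("HAC" %in% pyrl$kind)

  # amide N excluded from acceptors; carbonyl O accepts; N-H donates
  amide <- perceive_features(mol_from_smiles("CC(=O)NC", "amide")[[1]])
  expect_equal(sum(amide$kind == "HAC"), 1L)
  expect_equal(sum(amide$kind == "HDO"), 1L)

  # charged atoms produce POS/NEG
  chg <- perceive_features(mol_from_smiles("C[N+](C)(C)C", "tma")[[1]])
  expect_true("POS" %in% chg$kind)

  # an aliphatic >=3 carbon fragment is hydrophobic
  hex <- perceive_features(mol_from_smiles("CCCCCC", "hexane")[[1]])
  expect_equal(hex$kind, "HPB")
})

test_that("self-match has zero RMSD and alignment removes rigid motions", {
  lib <- gen_toy_library(4, seed = 3)
  for (k in seq_len(nrow(lib))) {
    mol <- lib$mol[[k]]
    f <- perceive_features(mol)
    if (nrow(f) < 2) next
    model <- pharmacophore_model(f, "self")
    m <- match_model(model, f)
    expect_true(m$matched)
    expect_equal(m$feature_rmsd, 0, tolerance = 1e-9)

    moved <- random_rigid_motion(mol, seed = 40 + k)
    fm <- perceive_features(moved)
    m2 <- match_model(model, fm, allow_alignment = TRUE)
    expect_true(m2$matched)
    expect_equal(m2$feature_rmsd, 0, tolerance = 1e-6)
  }
})

test_that("tolerance breaches and frame-sensitive matching behave", {
  f <- tibble::tibble(
    kind = c("HAC", "ARO", "HPB"),
    x = c(0, 3, 6), y = 0, z = 0)
  model <- pharmacophore_model(f, "toy")

  # ligand features: one HAC displaced 2.0 A beyond any compatible position
  lig <- f
  lig$radius <- NULL
  lig$x[1] <- lig$x[1] + 2.0 + 0.5
  expect_null(match_model(model, lig, allow_alignment = FALSE))

  # exact ligand in a translated frame: no-alignment match fails,
  # alignment recovers it
  shifted <- f
  shifted$x <- shifted$x + 8
  expect_null(match_model(model, shifted, allow_alignment = FALSE))
  m <- match_model(model, shifted, allow_alignment = TRUE)
  expect_true(m$matched)
  expect_equal(m$feature_rmsd, 0, tolerance = 1e-9)

  # required_count permits partial matches
  partial <- f[1:2, ]
  model2 <- pharmacophore_model(f, "toy2", required_count = 2)
  m2 <- match_model(model2, partial, allow_alignment = FALSE)
  expect_true(m2$matched)
  expect_equal(m2$n_matched, 2L)
})

test_that("property windows are inclusive and monotone under widening", {
  props <- tibble::tibble(
    id = "mid", mw = 440, tpsa = 90, logp = 3.0,
    n_rotatable = 6, n_hba = 7, n_hbd = 2, n_rings = 4)
  res <- property_filter(props)
  expect_true(res$pass)

  low_mw <- dplyr::mutate(props, mw = 400)
  res <- property_filter(low_mw)
  expect_false(res$pass)
  expect_false(res$mw_ok)
  expect_true(res$tpsa_ok)

  # inclusive boundary
  edge <- dplyr::mutate(props, mw = 416.81)
  expect_true(property_filter(edge)$mw_ok)

  # widening any window never flips pass -> fail
  set.seed(13)
  wide <- property_window(mw = c(0, 2000), tpsa = c(0, 500), logp = c(-5, 10),
                          n_rotatable = c(0, 50), n_hba = c(0, 50),
                          n_hbd = c(0, 50), n_rings = c(0, 50))
  for (k in 1:50) {
    p <- tibble::tibble(id = "r", mw = runif(1, 100, 900),
                        tpsa = runif(1, 0, 250), logp = runif(1, -3, 8),
                        n_rotatable = sample(0:20, 1), n_hba = sample(0:15, 1),
                        n_hbd = sample(0:10, 1), n_rings = sample(0:8, 1))
    if (property_filter(p)$pass) expect_true(property_filter(p, wide)$pass)
  }
})

test_that("computed properties feed the filter end to end", {
  lib <- gen_toy_library(3, seed = 21)
  res <- property_filter(lib, property_window(mw = c(100, 600),
                                              tpsa = c(0, 200),
                                              logp = c(-2, 8),
                                              n_rotatable = c(0, 15),
                                              n_hba = c(0, 12),
                                              n_hbd = c(0, 8),
                                              n_rings = c(0, 8)))
  expect_equal(nrow(res), 3L)
  expect_true(all(res$pass))
})

test_that("the steric filter applies vdW radii minus tolerance, floored", {
  # carbon vdW 1.70, tolerance 1.5 -> clash threshold 0.20 A
  rec <- tibble::tibble(element = "C", x = 0, y = 0, z = 0)
  at_01 <- matrix(c(0.1, 0, 0), 1)
  expect_false(steric_filter(at_01, rec, tolerance = 1.5))
  at_03 <- matrix(c(0.3, 0, 0), 1)
  expect_true(steric_filter(at_03, rec, tolerance = 1.5))

  far <- matrix(c(10, 0, 0), 1)
  expect_true(steric_filter(far, rec, tolerance = 1.5))

  # tolerance exceeding every vdW radius floors all thresholds at zero
  expect_true(steric_filter(matrix(0, 1, 3), rec, tolerance = 5))

  expect_error(steric_filter(far, rec[0, ], 1.5), "[Ee]mpty")
})

test_that("hits rank by feature RMSD with id tie-breaks", {
  hits <- tibble::tibble(id = c("c", "a", "b", "d"),
                         feature_rmsd = c(0.8, 0.2, 0.5, 0.2))
  ranked <- rank_hits(hits)
  expect_equal(ranked$id, c("a", "d", "b", "c"))
  expect_equal(nrow(rank_hits(hits[0, ])), 0L)
})

test_that("consensus features cluster by kind, support and merge radius", {
  f <- tibble::tibble(kind = c("HAC", "HAC", "ARO"),
                      x = c(0, 4, 2), y = 0, z = 0)
  # identical sets, min_support 1 -> the common set
  cm <- consensus_features(list(f, f, f), min_support = 1)
  expect_equal(nrow(cm$features), 3L)
  expect_setequal(cm$features$kind, c("HAC", "HAC", "ARO"))

  # a feature in 1 of 4 actives with min_support 0.5 is excluded
  extra <- dplyr::bind_rows(f, tibble::tibble(kind = "HPB", x = 9, y = 0, z = 0))
  cm <- consensus_features(list(f, f, f, extra), min_support = 0.5)
  expect_false("HPB" %in% cm$features$kind)

  # two HAC clusters 0.3 A apart merge within radius 1.0 at the centroid
  g1 <- tibble::tibble(kind = c("HAC", "ARO"), x = c(0, 5), y = 0, z = 0)
  g2 <- tibble::tibble(kind = c("HAC", "ARO"), x = c(0.3, 5), y = 0, z = 0)
  cm <- consensus_features(list(g1, g2), min_support = 1, merge_radius = 1.0)
  hac <- cm$features[cm$features$kind == "HAC", ]
  expect_equal(nrow(hac), 1L)
  expect_equal(hac$x, 0.15)

  expect_error(consensus_features(list(f), 0.5), "2")
})
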