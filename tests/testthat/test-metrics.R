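# Pose RMSD, quality bands, enrichment factor and ROC-AUC.

test_that("RMSD quality bands follow the 2/3 Angstrom convention", {
  expect_equal(as.character(classify_rmsd(1.144)), "consistent")
  expect_equal(as.character(classify_rmsd(3.108)), "inaccurate")
  expect_equal(as.character(classify_rmsd(2.5)), "deviated")
  expect_equal(as.character(classify_rmsd(c(2.0, 3.0))),
               c("deviated", "deviated"))  # band inclusive on both ends
  expect_equal(as.character(classify_rmsd(0)), "consistent")
  expect_error(classify_rmsd(-0.1))
})

test_that("in-place RMSD handles identity, translation and ring symmetry", {
  mol <- jittered_benzene(1)
  expect_equal(pose_rmsd(mol, mol)$rmsd, 0)

  shifted <- mol
  shifted$atoms$x <- shifted$atoms$x + 3
  cmp <- pose_rmsd(mol, shifted, "in_place")
  expect_equal(cmp$rmsd, 3.0, tolerance = 1e-12)
  expect_equal(cmp$quality, "deviated")

  # benzene rotated 60 degrees about its axis: atoms permute cyclically, so
  # automorphism matching recovers RMSD ~ 0 (flat reference, no jitter)
  benz <- mol_from_smiles("c1ccccc1", "benz")[[1]]
  rot <- benz
  th <- pi / 3
  xy <- cbind(rot$atoms$x, rot$atoms$y)
  cen <- colMeans(xy)
  xy <- sweep(xy, 2, cen) %*% matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  rot$atoms$x <- xy[, 1] + cen[1]
  rot$atoms$y <- xy[, 2] + cen[2]
  # tolerance reflects the 1e-4 A precision of generated 2D coordinates
  expect_lt(pose_rmsd(benz, rot, "in_place")$rmsd, 1e-3)
})

test_that("automorphism-minimized RMSD never exceeds the identity mapping", {
  lib <- gen_toy_library(6, seed = 5)
  for (k in seq_len(nrow(lib))) {
    mol <- lib$mol[[k]]
    pert <- gen_perturbed_pose(mol, sigma = 0.8, seed = k)
    identity_rmsd <- sqrt(mean(rowSums(
      (as.matrix(mol$atoms[, c("x", "y", "z")]) -
         as.matrix(pert$atoms[, c("x", "y", "z")]))^2)))
    expect_lte(pose_rmsd(mol, pert)$rmsd, identity_rmsd + 1e-12)
  }
})

test_that("superposed RMSD is invariant under rigid motions", {
  lib <- gen_toy_library(4, seed = 9)
  for (k in seq_len(nrow(lib))) {
    mol <- lib$mol[[k]]
    pert <- gen_perturbed_pose(mol, sigma = 0.3, seed = 10 + k)
    base <- pose_rmsd(mol, pert, "superposed")$rmsd
    moved <- random_rigid_motion(pert, seed = 20 + k)
    expect_equal(pose_rmsd(mol, moved, "superposed")$rmsd, base,
                 tolerance = 1e-6)
    # and the superposed value never exceeds the in-place one
    expect_lte(base, pose_rmsd(mol, pert, "in_place")$rmsd + 1e-9)
  }
})

test_that("pose comparison rejects mismatched molecules and tiny superpositions", {
  a <- mol_from_smiles("CCO", "a")[[1]]
  b <- mol_from_smiles("CCN", "b")[[1]]
  expect_error(pose_rmsd(a, b), "molecular graph")
  two <- mol_from_smiles("CO", "c")[[1]]
  expect_error(pose_rmsd(two, two, "superposed"), "3 atoms")
})

test_that("enrichment factor reproduces hand counts and the floor rule", {
  # pre-tabulated counts: (10/16) / (30/332)
  ef <- enrichment_from_counts(10, 16, 30, 332, 5)
  expect_equal(ef$ef, (10 / 16) / (30 / 332), tolerance = 1e-12)
  expect_equal(round(ef$ef, 3), 6.917)

  # perfect ranking reaches the theoretical maximum N/actives_total
  scores <- tibble::tibble(
    id = sprintf("c%03d", 1:100),
    score = seq(100, 1),
    active = c(rep(TRUE, 10), rep(FALSE, 90)))
  ef <- enrichment_factor(scores, x_pct = 5)
  expect_equal(ef$dataset_x, 5L)  # floor(5% of 100)
  expect_equal(ef$ef, 10)

  # floor: 5% of 332 inspects 16 compounds
  scores332 <- tibble::tibble(
    id = sprintf("c%03d", 1:332), score = runif(332),
    active = rep(c(TRUE, FALSE), c(30, 302)))
  expect_equal(enrichment_factor(scores332, 5)$dataset_x, 16L)

  expect_error(enrichment_factor(dplyr::mutate(scores332, active = FALSE), 5),
               "active")
  expect_error(enrichment_factor(scores332, 0.1), "empty")
})

test_that("enrichment under label permutation averages to 1", {
  set.seed(31)
  base <- gen_screen_set(screen_spec(n_actives = 30, n_decoys = 302, d = 2,
                                     seed = 8))
  efs <- replicate(400, {
    shuffled <- base
    shuffled$active <- sample(shuffled$active)
    enrichment_factor(shuffled, 5)$ef
  })
  # E[EF] = 1 exactly under the hypergeometric null; tolerate 3 SEs
  se <- sd(efs) / sqrt(length(efs))
  expect_lt(abs(mean(efs) - 1), 3 * se + 0.02)
})

test_that("AUC equals the brute-force ordered-pair fraction", {
  # hand example: actives {0.9, 0.4}, inactives {0.6, 0.1} -> 3/4 correct
  scores <- tibble::tibble(id = c("a1", "a2", "i1", "i2"),
                           score = c(0.9, 0.4, 0.6, 0.1),
                           active = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc_auc(scores)$auc, 0.75)

  # random instances vs brute force with half-credit ties
  set.seed(17)
  for (k in 1:20) {
    n <- sample(6:50, 1)
    tbl <- tibble::tibble(
      id = sprintf("x%02d", 1:n),
      score = sample(seq(0, 1, by = 0.1), n, replace = TRUE),
      active = c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE)))
    pos <- tbl$score[tbl$active]
    neg <- tbl$score[!tbl$active]
    brute <- mean(outer(pos, neg, function(p, q)
      (p > q) + 0.5 * (p == q)))
    expect_equal(roc_auc(tbl)$auc, brute, tolerance = 1e-12)
  }
})

test_that("AUC handles separation, ties, direction, and degenerate input", {
  sep <- tibble::tibble(id = letters[1:6], score = c(9, 8, 7, 3, 2, 1),
                        active = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(roc_auc(sep)$auc, 1.0)

  tied <- tibble::tibble(id = letters[1:6], score = 5,
                         active = rep(c(TRUE, FALSE), 3))
  expect_equal(roc_auc(tied)$auc, 0.5)

  asc <- dplyr::mutate(sep, score = -score)
  expect_equal(roc_auc(asc, direction = "asc")$auc, 1.0)

  expect_error(roc_auc(dplyr::mutate(sep, active = TRUE)), "inactive")

  curve <- roc_auc(sep)$curve
  expect_equal(curve$fpr[1], 0); expect_equal(curve$tpr[1], 0)
  expect_equal(curve$fpr[nrow(curve)], 1)
  expect_equal(curve$tpr[nrow(curve)], 1)
  expect_true(!is.unsorted(curve$fpr) && !is.unsorted(curve$tpr))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  tbl <- gen_screen_set(screen_spec(n_actives = 40, n_decoys = 160, d = 1.2,
                                    seed = 4))
  ours <- roc_auc(tbl)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = tbl$active, predictor = tbl$score,
    direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})
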