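# Fingerprints, Tanimoto, the similarity gate and target hypotheses.

test_that("atom-pair fingerprints follow the documented encoding", {
  # methane: no heavy-atom pair exists
  meth <- mol_from_smiles("C", "methane")[[1]]
  expect_length(compute_fingerprint(meth, "atom_pairs")$bits, 0L)

  # benzene: all carbons share one atom type, so the only distinct keys are
  # (aromatic C, aromatic C, d) for d in 1..3 -- derive them independently
  # from the documented encoding: type = elem_index*16 + degree*2 + aromatic,
  # key = (t1*1024 + t2)*64 + d, with C the 3rd element of the mass table
  benz <- mol_from_smiles("c1ccccc1", "benzene")[[1]]
  fp <- compute_fingerprint(benz, "atom_pairs")
  t_c <- 3 * 16 + 2 * 2 + 1
  expected <- sort((t_c * 1024 + t_c) * 64 + 1:3)
  expect_equal(fp$bits, expected)
})

test_that("equal structures give equal fingerprints regardless of spelling", {
  for (scheme in c("atom_pairs", "maccs")) {
    a <- compute_fingerprint(mol_from_smiles("C1=CC=CC=C1", "k")[[1]], scheme)
    b <- compute_fingerprint(mol_from_smiles("c1ccccc1", "a")[[1]], scheme)
    expect_equal(a$bits, b$bits)
    c1 <- compute_fingerprint(mol_from_smiles("OC(=O)C", "ac1")[[1]], scheme)
    c2 <- compute_fingerprint(mol_from_smiles("CC(O)=O", "ac2")[[1]], scheme)
    expect_equal(c1$bits, c2$bits)
  }
})

test_that("Tanimoto matches hand arithmetic and its axioms", {
  # a = 10, b = 8, c = 4 -> 4/14
  fa <- raw_fp(1:10)
  fb <- raw_fp(c(1:4, 101:104))
  s <- tanimoto(fa, fb)
  expect_equal(s$a, 10L)
  expect_equal(s$b, 8L)
  expect_equal(s$c, 4L)
  expect_equal(s$value, 4 / 14)
  expect_equal(tanimoto(fb, fa)$value, s$value)  # symmetry

  expect_equal(tanimoto(raw_fp(5:9), raw_fp(5:9))$value, 1.0)
  expect_equal(tanimoto(raw_fp(1:5), raw_fp(6:10))$value, 0.0)
  expect_error(tanimoto(raw_fp(1, "atom_pairs"), raw_fp(1, "maccs")),
               "mismatch")
  expect_warning(s0 <- tanimoto(raw_fp(numeric(0)), raw_fp(numeric(0))),
                 "empty")
  expect_equal(s0$value, 0.0)
})

test_that("Tanimoto metric properties hold across a generated library", {
  lib <- gen_toy_library(8, seed = 42)
  for (scheme in c("atom_pairs", "maccs")) {
    fps <- compute_fingerprint(lib, scheme)
    for (i in seq_along(fps)) {
      expect_equal(tanimoto(fps[[i]], fps[[i]])$value, 1.0)  # self-similarity
      for (j in seq_len(i - 1)) {
        sij <- tanimoto(fps[[i]], fps[[j]])
        sji <- tanimoto(fps[[j]], fps[[i]])
        expect_equal(sij$value, sji$value)
        expect_gte(sij$value, 0)
        expect_lte(sij$value, 1)
        if (sij$value == 1) expect_setequal(fps[[i]]$bits, fps[[j]]$bits)
      }
    }
  }
})

test_that("the dual-threshold gate is inclusive and monotone", {
  expect_true(similarity_gate(0.44, 0.62))
  expect_true(similarity_gate(0.237, 0.528))   # inclusive boundary
  expect_false(similarity_gate(0.236, 0.90))
  expect_false(similarity_gate(0.90, 0.527))

  # raising either value never flips pass -> fail
  set.seed(11)
  for (k in 1:200) {
    ap <- runif(1); mc <- runif(1)
    base <- similarity_gate(ap, mc)
    if (base) {
      expect_true(similarity_gate(min(1, ap + runif(1) * (1 - ap)), mc))
      expect_true(similarity_gate(ap, min(1, mc + runif(1) * (1 - mc))))
    }
  }

  strict <- gate_config(inclusive = FALSE)
  expect_false(similarity_gate(0.237, 0.528, strict))
})

test_that("target hypotheses carry the matched drug's targets, ordered", {
  drugs <- compound_library(
    c("CNC(=O)c1cc(Oc2ccc(NC(=O)Nc3ccc(Cl)c(C(F)(F)F)c3)cc2)ccn1",
      "COc1cc2ncnc(Nc3ccc(F)c(Cl)c3)c2cc1OCCCN1CCOCC1"),
    c("Sorafenib", "Gefitinib"))
  map <- tibble::tibble(
    drug_id = c("Sorafenib", "Sorafenib", "Gefitinib"),
    target_id = c("VEGFR-2", "RET", "EGFR"))

  # query identical to one reference drug
  query <- compound_library(drugs$smiles[1], "query1")
  hyp <- propose_targets(query, drugs, map)
  self_row <- hyp[hyp$drug_id == "Sorafenib", ]
  expect_equal(nrow(self_row), 1L)
  expect_equal(self_row$tani_ap, 1.0)
  expect_equal(self_row$tani_maccs, 1.0)
  expect_equal(self_row$proposed_targets[[1]], c("RET", "VEGFR-2"))

  # ordering: descending tani_ap first
  if (nrow(hyp) > 1) expect_true(!is.unsorted(rev(hyp$tani_ap)))

  # empty query library -> empty result
  empty <- propose_targets(query[0, ], drugs, map)
  expect_equal(nrow(empty), 0L)

  # unmapped drug -> error naming it
  expect_error(propose_targets(query, drugs, map[map$drug_id != "Gefitinib", ]),
               "Gefitinib")
})
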