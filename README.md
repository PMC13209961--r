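# kinscreen

Statistical triage and validation for kinase-inhibitor virtual screening.

Structure-based repurposing campaigns produce large tables of docking
results — per ligand a binding affinity (kcal/mol), a CNN pose score in
[0, 1] and a CNN affinity — and the hard part is rarely the docking itself
but the *decision layer*: which candidates are worth keeping, and how do you
know the protocol can be trusted? `kinscreen` implements that layer as a
tested, tidyverse-native R package for computational chemists running
screens against protein kinases (or any target family with a comparable
scoring scheme):

* **Similarity gating.** Tanimoto similarity `T = c / (a + b − c)` over two
  complementary fingerprint families — topological atom pairs and the public
  166 substructure keys (MACCS) — with a dual-threshold gate
  (`T_AP ≥ 0.237` and `T_MACCS ≥ 0.528` simultaneously by default) that
  promotes a reference drug's kinase targets to hypotheses for a query
  compound.
* **Threshold statistics.** From a benchmark of FDA-approved drugs docked
  against their own targets, *soft* thresholds are derived as one-sided 95%
  confidence limits of the pooled metric means (upper limit for affinity,
  lower limits for the two CNN metrics), and *hard* thresholds as the
  benchmark extremes (no candidate may score worse than the worst approved
  drug). Per-target *category overrides* replace the soft affinity bound for
  targets that generic docking systematically underestimates.
* **Triage.** A candidate is accepted iff it (i) meets at least two of the
  three soft thresholds and (ii) violates no hard bound. All comparisons
  inclusive, on unrounded values.
* **Validation.** Symmetry-aware heavy-atom pose RMSD (minimized over graph
  automorphisms, optionally over rigid motions) with the standard
  < 2 Å / 2–3 Å / > 3 Å quality bands; the enrichment factor
  `EF(x%) = (actives_x / dataset_x) / (actives_total / dataset_total)`; and
  tie-aware ROC-AUC.
* **Pharmacophore screening.** Rule-based feature perception (acceptors,
  donors, aromatic centroids, hydrophobic fragments, charges),
  tolerance-sphere matching with least-squares alignment and RMSD ranking,
  FDA-drug-derived drug-likeness windows, and a receptor steric filter.
* **Synthetic generators** emulating benchmark tables, active/decoy screens,
  perturbed poses and small compound libraries, so the entire pipeline is
  testable without a docking engine.

## Worked example

Derive thresholds from the bundled FDA kinase benchmark (48 drug–target
docking records over 10 kinases) and triage a screening table:

```r
library(kinscreen)

bench <- read_score_table(system.file("extdata/fda_kinase_benchmark.csv",
                                      package = "kinscreen"))
ts <- derive_thresholds(bench, override_targets = "EGFR")
ts
#> <threshold_set>
#>   soft: affinity <= -9.00, pose >= 0.843, CNN affinity >= 7.703  (alpha = 0.05, n = 48)
#>   hard: affinity <= -6.82, pose >= 0.526, CNN affinity >= 7.010
#>   overrides: EGFR: affinity <= -7.95

cand <- read_score_table(system.file("extdata/vegfr2_screen_candidates.csv",
                                     package = "kinscreen"))
dec <- triage_table(cand, ts)
glance(dec)
#> # A tibble: 1 × 4
#>       n n_accepted n_rejected n_hard_violations
#>   <int>      <int>      <int>             <int>
#> 1    14         14          0                 0
```

Every bundled VEGFR-2 candidate clears the rule: each passes at least two
soft thresholds (e.g. a pose score of 0.537 fails its soft bound 0.843 but
stays above the hard floor 0.526, so strong affinity and CNN affinity carry
the decision).

Validate a screen with the enrichment factor and ROC-AUC:

```r
screen <- gen_screen_set(screen_spec(n_actives = 30, n_decoys = 302,
                                     d = 2, seed = 1))
enrichment_factor(screen, x_pct = 5)
#> <enrichment> EF(5%) = 8.992  [13/30 actives in top 16 of 332]
roc_auc(screen)$auc
#> [1] 0.9296909
```

An EF(5%) of ~9 means the top 5% of the ranked list holds nine times more
actives than a random pick of the same size; `autoplot(roc_auc(screen))`
draws the ROC curve.

Symmetry-aware pose RMSD (a benzene ring rotated by 60° is the same pose):

```r
mol <- gen_toy_library(1, seed = 1)$mol[[1]]
pose_rmsd(mol, gen_perturbed_pose(mol, sigma = 0.5, seed = 2))
#> <pose_comparison> rmsd = 0.966 A over 19 atoms (in_place, consistent)
```

A thin command-line wrapper ships in `inst/cli/kinscreen.R`
(`thresholds`, `triage`, `enrich`, `rmsd`, `similarity`, `pharma`,
`simulate`, and `run --config cfg.yaml` for the full pipeline).

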