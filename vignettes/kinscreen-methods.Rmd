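---
title: "kinscreen: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kinscreen: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinscreen)
```

`kinscreen` implements the decision layer of a kinase-inhibitor virtual
screening campaign: similarity-based target-hypothesis generation,
statistically derived acceptance thresholds for docking scores, a
two-of-three triage rule, pose/enrichment validation metrics, and a
lightweight pharmacophore screen. This vignette explains each model, its
assumptions and tunable parameters, and records the design decisions made
where the design was genuinely open.

## The scoring scheme

All triage operates on three per-ligand docking metrics, mirroring the
output of CNN-rescored docking engines:

* **affinity** — empirical binding energy in kcal/mol; more negative is
  stronger;
* **CNN pose score** — a neural estimate of pose correctness in $[0, 1]$;
* **CNN affinity** — a neural estimate of binding strength (positive,
  unitless; roughly a pK scale).

A *score table* is a tibble with `ligand_id`, `target_id` and these three
columns; `(ligand_id, target_id)` pairs are unique. Parsing normalizes the
typographic minus (U+2212) that typeset tables carry, so transcribed
literature tables read correctly.

## Similarity gating

Candidate compounds are compared against FDA-approved reference drugs under
the Tanimoto coefficient $T = c/(a + b - c)$, where $a$ and $b$ count each
structure's fingerprint bits and $c$ the shared ones. Two complementary
fingerprint families are used, and a candidate passes the gate only if it
clears a threshold on **both**:

* atom pairs (topological), default threshold $T \ge 0.237$;
* 166 public substructure keys (MACCS), default threshold $T \ge 0.528$.

The joint defaults correspond to a high overall-similarity criterion on the
two families simultaneously; both are plain arguments of `gate_config()`
and the comparisons are inclusive. A compound passing the gate against a
drug inherits that drug's known targets as *hypotheses*
(`propose_targets()`), ordered deterministically by descending atom-pair
Tanimoto, then MACCS Tanimoto, then drug id.

**Fingerprint encoding.** Absolute Tanimoto values depend on the
fingerprint implementation, so the package fixes both encodings exactly.
MACCS keys are computed by OpenBabel's implementation of the public 166-key
set (via ChemmineOB). Atom pairs are computed in-package with the classic
Carhart construction: atom type = (element, heavy-neighbor count, aromatic
flag); key = ordered type pair plus topological shortest-path distance,
capped at 30 bonds; set semantics (presence, not counts). Benzene therefore
has exactly three atom-pair bits — (aromatic C, aromatic C) at distances 1,
2 and 3 — and methane none (no heavy-atom pair exists). Two empty
fingerprints are *defined* to have similarity 0, with a warning:
featureless structures should not look alike. Values computed with other
toolkits' dictionaries will differ in absolute terms; gate thresholds
should be recalibrated if another implementation is substituted.

## Soft and hard thresholds

Given a benchmark of approved drugs docked against their own targets
(`derive_thresholds()`), the acceptance thresholds are:

* **soft** — one-sided confidence limits at level $1-\alpha$ (default
  $\alpha = 0.05$) on the pooled benchmark means: for affinity the *upper*
  limit $\bar{x} + q_{1-\alpha}\, s/\sqrt{n}$ (a candidate should dock at
  least as well as the typical approved drug), and for the two CNN metrics
  the *lower* limits $\bar{x} - q_{1-\alpha}\, s/\sqrt{n}$;
* **hard** — the benchmark extremes: maximum affinity, minimum pose score,
  minimum CNN affinity. These are the worst values any approved drug
  achieved; scoring beyond them is disqualifying.

Pooling is deliberate: one set of limits over all drug–target records,
rather than per-target intervals, matches how the thresholds are used (a
single screening rule) and keeps $n$ large enough for a stable standard
error. The quantile $q_{1-\alpha}$ is the standard normal one by default —
at benchmark sizes around $n = 50$ the large-sample limit is the routine
choice in the field's statistical software, and it is what reproduces the
reference limits bundled with the package ($-9.00$, $0.843$, $7.702$ from
the 48-record FDA benchmark). `threshold_config(method = "student_t")`
gives the exact small-sample bound (slightly wider: $-8.99$, $0.843$,
$7.701$ on the same data) for small benchmarks. Note the ordering this
implies: the soft affinity bound lies *above* the pooled mean and *below*
the hard maximum.

**Category overrides.** For targets where rigid-receptor docking
systematically underestimates the affinity of known binders (e.g. kinases
with large conformational shifts between states), the pooled soft affinity
bound is unattainably strict while the CNN metrics remain informative.
`category_override()` substitutes the per-target mean benchmark affinity
(e.g. $-7.95$ for the bundled EGFR set) for the soft affinity threshold of
that target only; pose and CNN-affinity bounds are never overridden.
Overrides are looked up by `target_id` at evaluation time, never baked into
records.

**Reporting precision.** Thresholds are reported rounded to the printed
precision of the field (affinity 2 decimals, CNN metrics 3), but triage
always compares unrounded values.

## The triage rule

`triage_evaluate()` formalizes the two acceptance criteria:

1. at least **two of three** soft thresholds must be met
   (affinity $\le$ soft, pose $\ge$ soft, CNN affinity $\ge$ soft);
2. any metric that misses its soft threshold must still satisfy its hard
   bound; a single hard violation rejects outright.

All comparisons are inclusive: a pose score of exactly 0.843 is a soft
pass, and a CNN affinity of exactly 7.010 is not a hard violation. The rule
is monotone — improving any single metric can never turn acceptance into
rejection — and this is enforced by property tests. A third, qualitative
criterion used in practice (visual inspection of binding interactions)
cannot be automated from score tables; an `interaction_note` column is
carried through reports for curator text.

## Validation metrics

**Pose RMSD.** Heavy-atom RMSD between a reference and a reproduced pose,
minimized over the automorphisms of the element-colored bond graph so that
topologically equivalent atoms match (a phenyl flipped by 180° is the same
pose). Automorphisms are enumerated with igraph's VF2 on the colored graph,
capped at 10,000 (beyond the cap the identity mapping is used and a warning
raised). Two modes:

* `in_place` (default) — no superposition; both poses are assumed to sit in
  the receptor frame, the re-/cross-docking convention. Superposing first
  would understate docking error.
* `superposed` — additionally minimized over rigid motions by Kabsch
  least-squares (SVD with a determinant guard against reflections);
  requires ≥ 3 atoms.

Quality bands follow the standard convention: < 2.0 Å *consistent*,
2.0–3.0 Å *deviated* (inclusive on both ends), > 3.0 Å *inaccurate*.

**Enrichment factor.**
$EF_{x\%} = (actives_{x}/dataset_{x}) \,/\, (actives_{tot}/dataset_{tot})$
with $dataset_x = \lfloor x \cdot N / 100 \rfloor$ — the floor reproduces
the conventional "16 of 332 at 5%" slice. Ranking direction is explicit per
metric (descending for the CNN metrics, ascending for affinity); score ties
break by stable id order. Under random ranking $E[EF] = 1$ exactly (the
count in the top slice is hypergeometric).

**ROC-AUC** is the tie-aware rank statistic: the fraction of
(active, inactive) pairs ordered correctly with half credit for ties,
computed from midranks; the curve is the usual threshold sweep from (0, 0)
to (1, 1). The test suite cross-checks the statistic against a brute-force
pair count and an independent ROC implementation (pROC).

## Pharmacophore screening

**Feature perception** (`perceive_features()`) is rule-based on the
heavy-atom graph — the package deliberately ships an explicit, versioned
rule set rather than delegating to undisclosed commercial perception, so
results are reproducible within the artifact:

| kind | rule | radius (Å) |
|------|------|-----------|
| HAC | N/O with a lone pair; excludes amide N, aromatic N–H, positive atoms | 0.5 |
| HDO | O–H or N–H | 0.5 |
| ARO | centroid of each aromatic ring | 1.1 |
| HPB | centroid of each connected fragment of ≥ 3 non-aromatic carbons with no heteroatom neighbor | 1.0 |
| POS/NEG | formally charged atoms at the input protonation (no pKa model) | 0.75 |

The HAC/HDO/ARO/HPB radii are the conventional display tolerances for these
feature classes; POS/NEG, for which no convention was available, were set
between the tight polar radii and the loose hydrophobic one.

Aromaticity is perceived from Kekulé patterns: a six-ring whose internal
double bonds form a perfect matching, or a five-ring with two internal
doubles and a lone-pair heteroatom (N/O/S) at the uncovered position. This
covers benzene, pyridine, pyrrole, furan, thiophene, imidazole and ordinary
fused systems, but not exotic cases (pyridones, azulenes, charged
aromatics); it is a documented simplification, adequate for the kekulized
structures OpenBabel emits.

**Matching** (`match_model()`) enumerates injective, kind-compatible
correspondences between model and ligand features, pruned by pairwise
distance compatibility (two model features may only map to ligand features
whose separation differs by at most the sum of the two tolerance radii).
Each surviving correspondence is aligned by Kabsch least squares (unless
matching in a shared receptor frame) and accepted when every matched pair
lies within the model feature's radius; the result minimizes feature RMSD,
preferring more matched features first. The search caps at $10^5$ candidate
assignments; beyond the cap the result is flagged *inconclusive* rather
than silently truncated. `required_count` allows partial matches. Hits are
ranked by ascending feature RMSD with id tie-breaks (`rank_hits()`).

**Consensus models** (`consensus_features()`) greedily cluster same-kind
features of aligned actives within a merge radius (default 1.0 Å) and keep
clusters supported by at least `min_support` of the actives. The reported
`support` fraction is a transparent surrogate for proprietary
model-quality scores and is not comparable to them.

**Steric filter** (`steric_filter()`): a pose is rejected when any ligand
heavy atom sits closer to a receptor atom than
$\max(0,\; r_\mathrm{vdW} - tolerance)$, with Bondi van der Waals radii and
a default tolerance of 1.5, interpreted as Å (the common "shape tolerance"
is unitless in some tools; the exclusion-sphere reading in Å is implemented
and stated here). Large tolerances floor every threshold at zero, accepting
everything.

**Drug-likeness windows** (`property_filter()`): inclusive intervals on MW,
TPSA, logP, rotatable bonds, H-bond acceptors/donors and ring count. The
defaults delimit the property space of the FDA-approved kinase-inhibitor
reference set (MW 416.81–461.47 Da, TPSA 83.48–95.83 Å², logP 2.62–3.49,
nRB 5–7, nHA 4–10, nHD 0–5, nRings 4–5); all are overridable. Conventions:
MW/TPSA (Ertl)/logP (atomic contribution) from OpenBabel; nHA/nHD reuse the
HAC/HDO perception rules; nRB counts non-ring single bonds between
non-terminal heavy atoms; nRings is the SSSR count (cyclomatic number).

## Synthetic generators

The generators produce data with the statistical structure the analysis
assumes — not physically realistic docking output:

* `gen_benchmark()` — per-target normal draws for the three metrics. The
  default composition mirrors a ten-kinase FDA benchmark (2–10 drugs per
  target, per-target mean affinities −10.4 to −7.9 kcal/mol); the
  dispersions (SD 1.3 kcal/mol, 0.08 pose, 0.3 CNN affinity) are
  illustrative choices of the same order as the reference table's spread.
  Pose scores are truncated to $[0, 1]$ (truncation, not resampling; at the
  shipped SDs the bias is < 0.002).
* `gen_screen_set()` — the binormal screen: decoys $N(\mu, \sigma)$,
  actives shifted by $d$ SDs, under which the expected AUC is
  $\Phi(d/\sqrt{2})$ — the closed form the validation tests check against.
  Real screens have heavier tails, correlated scores and property-matched
  decoys; passing these tests shows the *metrics* are computed correctly,
  not that any docking protocol discriminates.
* `gen_perturbed_pose()` — i.i.d. Gaussian coordinate noise;
  $E[\mathrm{RMSD}^2] = 3\sigma^2$ anchors the RMSD tests.
* `gen_toy_library()` — kinase-inhibitor-like scaffolds (anilinoquinazolines,
  aryl ureas, anilides) with randomized substituents; valid SMILES by
  construction.

Every generator is a pure function of (spec, seed): the seed is applied
locally and the caller's RNG state restored, so pipelines are reproducible
end to end from a single seed.

## Numerical and I/O choices

* Coordinates are Å in right-handed PDB/SDF convention; SDF is written at
  the molfile field precision (1e-4 Å), so round trips agree to well within
  1e-3 Å. V3000 input is rejected with a clear message.
* Hydrogens are dropped everywhere on read and folded into per-atom counts;
  all RMSD and feature work is heavy-atom. Implicit hydrogens are inferred
  from standard valences adjusted by formal charge.
* PDB ligands (HETATM records) carry no bond orders, so bonds are inferred
  by a covalent-radius rule (bonded below 1.25 × the radius sum); SDF input
  keeps its explicit bond table.
* Degenerate inputs fail loudly: empty benchmarks, single-record SD,
  single-class ROC input, empty top slices, unmapped drugs and malformed
  lines all raise errors naming the offender.

## Problem sizes and test design

The test suite regenerates every fixture in code. Distributional checks use
sizes chosen to keep the suite fast while leaving comfortable statistical
margins: 2,000 replicates for the 95% coverage check (±2% tolerance against
a binomial SE of ~0.5%), 4,000 + 4,000 compounds for the binormal AUC law
(±0.02 against an SE of ~0.005), and 500 label permutations for the null
enrichment mean (3 SE tolerance). The acceptance script
(`scripts/acceptance.R`) recomputes all headline quantities from scratch at
the same sizes.

## Known limitations

* Aromaticity and feature perception are simplified rule sets; unusual
  tautomers, charged aromatics and exotic heterocycles may be
  mis-perceived. The rules are versioned with the package so results are
  stable and auditable.
* No pKa/protonation model: POS/NEG features reflect the input structure.
* Atom-pair and MACCS values are implementation-specific; gate thresholds
  calibrated on one toolkit's fingerprints do not transfer bit-exactly to
  another's.
* The pharmacophore matcher enumerates correspondences and is intended for
  models of ≲ 10 features, not dense feature clouds.
* Conformers are taken as given; there is no conformer generation or
  flexible alignment.
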