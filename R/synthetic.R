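# Synthetic generators emulating the statistical structure of docking output,
# so every pipeline stage is testable without a docking engine.
#
# All generators are pure functions of (spec, seed): the seed is applied
# locally and the previous RNG state restored on exit.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic docking benchmark
#'
#' Per-target normal score distributions. The shipped default mirrors the
#' structure of an FDA kinase-inhibitor benchmark: ten targets of 2-10 drugs
#' each with per-target mean affinities between -10.4 and -7.9 kcal/mol, pose
#' score means around 0.85 and CNN affinity means around 7.8; the dispersions
#' are illustrative choices, not measured truth.
#'
#' @param targets Tibble with columns `target_id`, `n_drugs`, `mean_affinity`,
#'   `sd_affinity`, `mean_pose`, `sd_pose`, `mean_cnn_affinity`,
#'   `sd_cnn_affinity`.
#' @param seed Integer seed.
#' @return A `benchmark_spec`.
#' @export
benchmark_spec <- function(targets = default_benchmark_targets(), seed = 1L) {
  targets <- tibble::as_tibble(targets)
  need <- c("target_id", "n_drugs", "mean_affinity", "sd_affinity",
            "mean_pose", "sd_pose", "mean_cnn_affinity", "sd_cnn_affinity")
  missing <- setdiff(need, names(targets))
  if (length(missing))
    stop("benchmark_spec targets missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  stopifnot(all(targets$n_drugs >= 1),
            all(targets$sd_affinity >= 0), all(targets$sd_pose >= 0),
            all(targets$sd_cnn_affinity >= 0))
  structure(list(targets = targets, seed = as.integer(seed)),
            class = "benchmark_spec")
}

#' Default synthetic benchmark composition
#'
#' @return A targets tibble for [benchmark_spec()].
#' @export
default_benchmark_targets <- function() {
  tibble::tibble(
    target_id = c("VEGFR-2", "PDGFRa", "c-MET", "RET", "EGFR",
                  "HER2", "JAK1", "JAK2", "BTK", "BCR-Abl"),
    n_drugs = c(10L, 2L, 3L, 4L, 5L, 5L, 4L, 5L, 4L, 6L),
    mean_affinity = c(-9.77, -7.87, -10.13, -9.00, -7.95,
                      -9.09, -9.03, -8.47, -10.44, -10.38),
    sd_affinity = 1.3,
    mean_pose = c(0.882, 0.892, 0.912, 0.820, 0.945,
                  0.842, 0.847, 0.938, 0.852, 0.762),
    sd_pose = 0.08,
    mean_cnn_affinity = c(7.765, 8.079, 8.129, 7.572, 8.027,
                          7.590, 7.611, 7.856, 7.607, 7.771),
    sd_cnn_affinity = 0.3
  )
}

#' Generate a synthetic docking benchmark
#'
#' Per-target normal draws for the three metrics; pose scores are truncated
#' to \[0, 1\] (truncation, not resampling -- the bias is negligible at the
#' shipped dispersions).
#'
#' @param spec A [benchmark_spec()].
#' @return A validated score tibble.
#' @export
gen_benchmark <- function(spec) {
  stopifnot(inherits(spec, "benchmark_spec"))
  .with_seed(spec$seed, {
    rows <- purrr::pmap(spec$targets, function(target_id, n_drugs,
                                               mean_affinity, sd_affinity,
                                               mean_pose, sd_pose,
                                               mean_cnn_affinity,
                                               sd_cnn_affinity) {
      tibble::tibble(
        ligand_id = sprintf("%s_drug%02d", target_id, seq_len(n_drugs)),
        target_id = target_id,
        affinity = stats::rnorm(n_drugs, mean_affinity, sd_affinity),
        cnn_pose_score = pmin(1, pmax(0, stats::rnorm(n_drugs, mean_pose,
                                                      sd_pose))),
        cnn_affinity = pmax(.Machine$double.eps,
                            stats::rnorm(n_drugs, mean_cnn_affinity,
                                         sd_cnn_affinity))
      )
    })
    score_table(dplyr::bind_rows(rows))
  })
}

#' Specification for a labeled active/decoy screen
#'
#' Decoy scores are N(mean, sd); active scores are shifted up by `d` standard
#' deviations, the binormal separation under which the expected ROC-AUC is
#' `pnorm(d / sqrt(2))`. The default emulates a screen of 302 decoys and 30
#' actives.
#'
#' @param n_actives,n_decoys Compound counts (>= 1).
#' @param d Active score shift in SD units.
#' @param mean,sd Decoy score distribution.
#' @param seed Integer seed.
#' @return A `screen_spec`.
#' @export
screen_spec <- function(n_actives = 30L, n_decoys = 302L, d = 2.0,
                        mean = 6.5, sd = 0.5, seed = 1L) {
  stopifnot(n_actives >= 1, n_decoys >= 1, sd >= 0)
  structure(list(n_actives = as.integer(n_actives),
                 n_decoys = as.integer(n_decoys),
                 d = d, mean = mean, sd = sd, seed = as.integer(seed)),
            class = "screen_spec")
}

#' Generate a labeled active/decoy score set
#'
#' @param spec A [screen_spec()].
#' @return A tibble with `id`, `score`, `active` (larger scores rank better).
#' @export
gen_screen_set <- function(spec) {
  stopifnot(inherits(spec, "screen_spec"))
  .with_seed(spec$seed, {
    tibble::tibble(
      id = c(sprintf("active%04d", seq_len(spec$n_actives)),
             sprintf("decoy%04d", seq_len(spec$n_decoys))),
      score = c(stats::rnorm(spec$n_actives, spec$mean + spec$d * spec$sd,
                             spec$sd),
                stats::rnorm(spec$n_decoys, spec$mean, spec$sd)),
      active = rep(c(TRUE, FALSE), c(spec$n_actives, spec$n_decoys))
    )
  })
}

#' Perturb a conformer with isotropic Gaussian noise
#'
#' Adds i.i.d. N(0, sigma^2) displacement to every coordinate of every heavy
#' atom; for many atoms the in-place RMSD to the original concentrates near
#' `sigma * sqrt(3)`.
#'
#' @param mol A `mol_graph` with conformer.
#' @param sigma Displacement SD in Angstrom (>= 0).
#' @param seed Integer seed.
#' @return The perturbed `mol_graph`.
#' @export
gen_perturbed_pose <- function(mol, sigma, seed = 1L) {
  stopifnot(inherits(mol, "mol_graph"), sigma >= 0)
  .with_seed(seed, {
    n <- nrow(mol$atoms)
    mol$atoms$x <- mol$atoms$x + stats::rnorm(n, 0, sigma)
    mol$atoms$y <- mol$atoms$y + stats::rnorm(n, 0, sigma)
    mol$atoms$z <- mol$atoms$z + stats::rnorm(n, 0, sigma)
    mol
  })
}

#' Generate a toy compound library
#'
#' Draws from a small template grammar of kinase-inhibitor-like scaffolds
#' (substituted quinazolines, aryl ureas, anilides, biaryl amides) with
#' randomized substituents. All SMILES are valid by construction.
#'
#' @param n Number of compounds (>= 1).
#' @param seed Integer seed.
#' @return A compound-library tibble (see [compound_library()]).
#' @export
gen_toy_library <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  scaffolds <- c(
    "c1ccc2ncnc(N%s)c2c1",            # 4-anilinoquinazoline core
    "c1ccc(NC(=O)Nc2ccc(%s)cc2)cc1",  # diaryl urea
    "c1ccc(C(=O)Nc2ccc(%s)cc2)cc1",   # benzanilide
    "c1ccc(-c2ccc(NC(=O)C%s)cc2)cc1", # biaryl acetamide
    "c1ccc(Oc2ccnc(N%s)c2)cc1"        # aryloxy-pyridine amine
  )
  # ring-closure digit 3 avoids collision with the scaffold's open rings
  subst <- c("C", "CC", "CCO", "c3ccccc3", "C(F)(F)F", "CCN(C)C",
             "c3ccncc3", "CC(C)C")
  .with_seed(seed, {
    smiles <- vapply(seq_len(n), function(k) {
      sprintf(sample(scaffolds, 1), sample(subst, 1))
    }, character(1))
    compound_library(smiles, id = sprintf("toy%04d", seq_len(n)))
  })
}
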