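Package: kinscreen
Title: Statistical Triage and Validation for Kinase-Inhibitor Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the decision layer of
    structure-based drug repurposing campaigns against protein kinases.
    Implements dual-fingerprint Tanimoto similarity gating for target-hypothesis
    generation, derivation of soft (one-sided Student-t confidence limit) and
    hard (benchmark extreme value) acceptance thresholds from FDA-drug docking
    benchmarks, the two-of-three triage rule for candidate docking scores,
    symmetry-aware pose RMSD with the 2/3 Angstrom quality bands, enrichment
    factor and ROC-AUC screen validation, and a lightweight pharmacophore
    representation with feature perception, tolerance-sphere matching,
    drug-likeness property windows and a receptor steric filter. Synthetic
    generators emulate docking output so the full pipeline is testable without
    a docking engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
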