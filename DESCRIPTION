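Package: resifc
Title: Seed-Based Residual Functional Connectivity Analysis of Cognitive Fatigue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for task-independent (residual)
    seed-based functional connectivity modulated by state cognitive fatigue.
    Generates synthetic n-back BOLD runs with planted fatigue-dependent
    seed-target coupling, computes motion and signal confound metrics
    (framewise displacement, standardized DVARS, tissue mean signals),
    fits a first-level deconvolution GLM whose saved residuals carry the
    fatigue-related signal, builds per-run seed-based Fisher-z connectivity
    maps, relates them to fatigue ratings with voxelwise linear mixed-effects
    models, and controls familywise error with Monte-Carlo cluster-extent
    calibration. Includes the behavioral arm: run-level fatigue scores,
    Box-Cox transformation, mixed models and Tukey-adjusted contrasts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    data.table,
    lme4,
    lmerTest,
    emmeans,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
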