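Package: dynfc
Title: Sliding-Window Dynamic ALFF and Seed-Based Dynamic Functional
    Connectivity for Resting-State fMRI Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Region-of-interest level analysis of resting-state fMRI
    dynamic connectivity. Provides deterministic signal conditioning
    (initial-volume trimming, motion-exclusion flagging, linear
    detrending, nuisance regression, zero-phase band-pass filtering),
    sliding-window mean dynamic amplitude of low-frequency fluctuation
    (mdALFF mean and variance per ROI), seed-based sliding-window
    functional connectivity on the Fisher-Z scale, covariate-adjusted
    group contrasts with dual false-discovery-rate families (whole-brain
    and per-network), network-based statistic permutation testing,
    partial correlations with clinical scores and Fisher-Z comparison of
    correlations between groups, a synthetic-cohort generator with
    controllable group effects for validation, and a file-based pipeline
    orchestrator with a reproducibility manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
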