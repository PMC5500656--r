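Package: rsfcs
Title: Resting-State Functional Connectivity Strength Mapping and Group Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-wise resting-state functional connectivity strength (FCS)
    analysis for 4D BOLD data: subject-level temporal preprocessing (initial
    volume discard, motion QC, nuisance regression, ideal band-pass), weighted
    degree-centrality maps partitioned into long- and short-range components at
    an anatomical distance cutoff, covariate-adjusted voxel-wise group
    inference with Monte-Carlo (AlphaSim-style) cluster-extent correction,
    seed-based connectivity follow-up, and ROI-level clinical statistics
    (partial correlations, Fisher r-to-z group comparison, Bonferroni,
    demographics tests). Includes a synthetic two-group BOLD phantom generator
    with known block correlation structure and plantable group effects, so the
    whole pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    nortest,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
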