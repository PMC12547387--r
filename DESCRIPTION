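Package: sparsemion
Title: Sparse-Sampling MION fMRI Analysis: GLM, Random-Field Inference and
    Run Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for auditory task fMRI acquired
    with a blood-pool contrast agent (MION) under a clustered sparse temporal
    sampling design. Provides a synthetic-cohort generator emulating the
    acquisition protocol (stimulus blocks in scanner-silent gaps, 7-volume
    acquisition clusters, onset jitter, reversed-sign contrast-agent
    hemodynamics, AR(1) and drift noise, compartment-confined nuisance
    components); a reversed-sign gamma-variate response function and task
    regressor construction at non-uniform acquisition times; CompCor-style
    white-matter/CSF principal-component nuisance regression with
    component-count optimisation; per-run prewhitened GLM fitting with
    contrast maps and inverse-variance run combination; fixed- and
    random-effects group maps with Gaussian-random-field peak and
    cluster-size multiple-comparison correction; jackknife leave-one-run-out
    run selection; and sphere/intersection ROI definition with per-subcategory
    t-profile extraction.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
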