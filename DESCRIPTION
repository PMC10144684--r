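Package: coclin
Title: Co-Clinical Trial Imaging and Omics Analysis Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical core for co-clinical (matched patient and
    patient-derived xenograft) treatment-response studies. Computes
    voxel-wise quantitative MRI parameter maps (apparent diffusion
    coefficient from multi-b-value diffusion series, signal enhancement
    ratio from dynamic contrast-enhanced series), extracts lesion-level
    imaging biomarkers (longest diameter, volume, mean/median map values),
    builds baseline-versus-follow-up response tables and waterfall
    orderings, simulates on-treatment expression matrices by per-sample
    four-factor count perturbation, and associates imaging features with
    gene expression through ranked Spearman statistics with top/bottom
    gene lists, cross-cohort overlap, and volcano-plot data. Includes a
    digital phantom generator with analytic ground truth for validation,
    NIfTI + JSON sidecar and TSV input/output, and a deterministic
    end-to-end pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    ggplot2,
    jsonlite,
    rlang,
    RNifti,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
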