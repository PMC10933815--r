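Package: rsnamp
Title: Decomposing Resting-State Network Amplitude into Temporal Synchrony
    and BOLD Fluctuation Amplitude
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study the amplitudes of resting-state fMRI networks.
    Extracts per-subject network timeseries by stage-1 dual regression
    against group spatial maps and decomposes each network's amplitude (the
    SD of its timeseries) into temporal synchrony (the same statistic after
    z-scoring every voxel) and voxelwise BOLD fluctuation amplitude
    (summaries of per-voxel SDs over strongly weighted voxels). Includes
    partial-correlation network matrices with absolute/positive/negative
    summary connectivity, Ward clustering of the intersubject
    amplitude-covariation matrix, regression-based deconfounding,
    soft-shrinkage SVD imputation, mass univariate correlation with
    stringent thresholds, comparison of overlapping dependent correlations,
    and multiple linear regressions with an age/sex design; all driven by a
    synthetic cohort generator with planted, independently controllable
    synchrony, amplitude, connectivity and phenotype-effect structure.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    RNifti,
    withr,
    yaml
Config/testthat/edition: 3
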