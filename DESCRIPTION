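Package: alffkit
Title: Amplitude of Low-Frequency Fluctuation Analysis for Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("alffkit", "maintainers", email = "maintainers@alffkit.dev",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for resting-state fMRI amplitude of
    low-frequency fluctuation (ALFF) analysis: minimal NIfTI-1 input/output,
    initial-volume discard, motion quality control, Gaussian spatial
    smoothing, ideal band-pass filtering, voxel-wise ALFF and global-mean
    standardization, voxel-wise two-sample inference with permutation
    cluster-level family-wise error correction, grey-matter image and scalar
    covariate adjustment, MNI-to-Talairach peak reporting, volume-of-interest
    extraction and clinical correlation, plus a synthetic 4D cohort generator
    with planted, recoverable effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
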