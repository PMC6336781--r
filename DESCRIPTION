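Package: rsmvpa
Title: Resting-State fMRI Parameter Maps and Individual Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, denoising and voxelwise analysis of resting-state
    BOLD fMRI for two-group individual classification. Generates synthetic
    two-group cohorts with controllable regional effects, implements a
    motion-aware nuisance-regression and bandpass denoising chain, computes
    four intrinsic-activity parameter maps (amplitude of low-frequency
    fluctuations, its fractional variant, regional homogeneity via Kendall's
    coefficient of concordance, and functional connectivity strength), and
    evaluates their diagnostic value with voxelwise two-sample statistics
    under false-discovery-rate control and a linear-kernel support vector
    machine with leave-one-pair-out cross-validation, permutation
    significance testing and discrimination maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    e1071,
    stats,
    utils
Suggests:
    kernlab,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
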