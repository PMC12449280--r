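Package: invertseg
Title: Cross-Modality Segmentation Transfer to MRI via Intensity Inversion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for reusing computed-tomography segmentation models on
    magnetic-resonance images by intensity-inversion preprocessing. Implements
    clipping and inversion with first-percentile background zeroing, isotropic
    resampling of NIfTI volumes and label maps, a pluggable segmentation
    backend (a rule-based intensity-window segmenter and an external-command
    adapter), class-wise Dice evaluation with bootstrap confidence intervals,
    tumor localization and volume-stratified analyses, paired Wilcoxon
    signed-rank comparisons with Benjamini-Hochberg correction, and a seeded
    synthetic multi-modality abdominal phantom generator that drives
    end-to-end experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
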