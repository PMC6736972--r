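Package: painmediate
Title: Multilevel Mediation of Social and Conditioned Cue Effects on Pain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for dissociating the effects of social information and
    classically conditioned cues on pain via multilevel (two-level summary
    statistics) mediation analysis. Implements single-trial estimation rules
    (recursive outlier time-point detection, single-trial GLM design with
    variance-inflation-factor exclusion, skin-conductance deconvolution),
    subject-level three-path mediation with bias-corrected bootstrap group
    inference, voxelwise mediation maps with Benjamini-Hochberg FDR
    thresholding, display pruning and conjunction-null analysis, network-level
    spatial decoding (wedge similarity, z-scored subnetwork contrasts,
    octant/sum-of-squared-distance covariation, term-map decoding),
    leave-one-subject-out forced-choice pattern classification, and a
    synthetic-data generator that emulates the full experimental design with
    known planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    signal,
    e1071,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
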