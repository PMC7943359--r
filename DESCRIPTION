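Package: stereorsa
Title: Stereotype-Biased Face Perception and Neural Representational Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying how gender-emotion
    stereotypes bias subjective face perception and its neural representational
    structure. Implements mouse-tracking trajectory preprocessing and maximum
    perpendicular deviation, stereotype-strength scoring from descriptor
    ratings, subjective and model dissimilarity matrices, multi-level (GEE)
    regression of trajectory deviation, signal-detection analysis of masked
    discrimination, gamma-HRF GLM pattern estimation, ROI and searchlight
    representational similarity analysis with sign-flip max-statistic
    permutation inference, and psychophysiological interaction (PPI)
    connectivity analysis, together with a synthetic-data generator that
    plants known effect structure for parameter-recovery validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    sandwich
Config/testthat/edition: 3
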