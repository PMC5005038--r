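Package: hexadir
Title: Hexadirectional and Head-Direction Pattern Similarity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting grid-cell-like (six-fold, 60-degree periodic)
    and head-direction-like (one-fold) codes in multi-voxel activity patterns
    recorded while participants imagine directions between landmarks. Implements
    the hexagonal building layout and counterbalanced direction-sampling design,
    a synthetic cohort generator with planted grid, head-direction or null
    tuning, nuisance-GLM residualization and trial-window pattern extraction,
    pairwise Pearson/Fisher-z representational similarity with modulo-60,
    modulo-90, one-fold and cardinal contrasts and their exclusion and
    distance-residualization controls, volumetric searchlight mapping, and
    subject- and group-level permutation inference with calibration harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    grDevices,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
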