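Package: bpemri
Title: Quantitative Breast Density and Background Parenchymal Enhancement
    from Breast DCE-MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A semi-automated pipeline for quantitative analysis of breast
    MRI: seeded 3D region-growing whole-breast masking with morphological
    skin/chest-wall erosion, smooth multiplicative bias-field correction,
    fuzzy c-means fibro-glandular tissue segmentation, MRI breast density
    (MRBD), voxelwise background parenchymal enhancement (BPE) mapping with
    distribution summaries, and the associated repeatability, agreement
    (Bland-Altman) and group-comparison statistics. Includes a digital
    DCE breast phantom generator with known ground truth (spoiled
    gradient-echo signal model, type I enhancement kinetics, bias field,
    noise) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    oro.nifti,
    optparse,
    knitr
Config/testthat/edition: 3
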