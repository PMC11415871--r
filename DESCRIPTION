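Package: vasarify
Title: Deterministic VASARI Featurisation of Glioma Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives the VASARI (Visually AcceSAble Rembrandt Images) glioma
    MRI feature set from multi-channel lesion segmentation masks held in a
    common template space, using only deterministic voxel geometry (atlas
    overlap, connected components, hole filling, Euclidean distance
    transforms). Also provides the surrounding evaluation machinery:
    inter-rater agreement statistics (Dice, linearly weighted Cohen's kappa,
    balanced accuracy) with equity stratification by sex and age decade, a
    Monte Carlo workforce and cost simulation for multidisciplinary-team
    caseloads, ordinary least-squares survival regression with
    variance-inflation-factor pre-filtering, and a synthetic phantom
    generator with construction-guaranteed ground truth for end-to-end
    testing without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    broom
Config/testthat/edition: 3
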