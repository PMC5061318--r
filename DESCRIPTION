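Package: multipose
Title: Multi-Pose Larval Zebrafish Brain Imaging Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-pose high-content imaging of larval
    zebrafish brains in 96-well plates. Localizes the larval brain from paired
    bright-field/fluorescence well images (circular Hough head detection,
    Otsu+PCA orientation normalization, matched-filter eye detection,
    landmark-based brain cropping), segments fluorescent neurons and computes a
    Brain Health Score against an idealized template, and provides the
    screening-quality statistics (Z'-factor, robust Z'-factor, SSMD*, power and
    sample-size analysis, bootstrap group averaging) used to qualify such an
    assay. Includes a ground-truthed synthetic larva image generator so the
    whole pipeline can be exercised and validated without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    tiff,
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    jsonlite,
    yaml,
    withr,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
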