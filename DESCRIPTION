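Package: tissueqc
Title: Non-Destructive Quality Assessment of Engineered Tissue by
    Fluorescence Lifetime and Ultrasound Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for label-free, non-destructive quality control
    of tissue-engineered constructs. Builds per-channel fluorescence-lifetime
    (FLIm) maps from raw decay waveforms, reconstructs 8-bit B-mode images from
    high-frequency ultrasound backscatter (UBM) RF data, segments total-sample
    and void regions to obtain percent void volume, combines structural and
    biochemical homogeneity into a single homogeneity index, fits biphasic
    stress-relaxation and tensile records for mechanical reference values, and
    links optical to destructive measurements through linear calibrations and
    Lin's concordance correlation. Seeded synthetic phantoms with known ground
    truth are provided for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    minpack.lm,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tiff,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
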