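Package: pcctstab
Title: Radiomics Feature Stability in Spectral Photon-Counting CT Reconstructions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study the stability of radiomics texture features across
    spectral reconstructions of abdominal photon-counting CT. Simulates
    multi-reconstruction phantom cohorts (virtual monoenergetic 40-120 keV,
    polyenergetic, virtual non-contrast and iodine-map channels over shared
    patient anatomy), places disk and sphere regions of interest in six tissue
    classes, extracts the 93-feature non-shape radiomics bank (first-order,
    GLCM, GLRLM, GLSZM, GLDM, NGTDM) under fixed-bin-width discretization, and
    screens features for energy independence and segmentation-resegmentation
    stability with ICC(3,1), Lin's concordance correlation coefficient and
    repeated-measures ANOVA with Greenhouse-Geisser correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    RNifti,
    jsonlite,
    yaml,
    ape,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
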