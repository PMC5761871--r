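Package: lungquant
Title: Micro-CT Lung Densitometry and Automated H&E Histomorphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantification of interstitial lung disease in small-animal
    micro-CT: seeded region-growing lung segmentation with morphological
    refinement, conducting-airway extraction with distance-transform
    diameter measurement and size exclusion, Hounsfield-unit histogram
    densitometry (weighted mean density, aerated/tissue volume partition,
    CTDI dose summaries), Gaussian-discriminant classification of H&E
    slides into nuclei/tissue/air compartments with area outcomes, and the
    cohort statistics used to validate imaging against histology
    (rank-transformed two-way ANOVA, Bonferroni-corrected timepoint tests,
    Spearman correlation). Includes synthetic CT and H&E phantom
    generators with exact ground truth so the full pipeline is testable
    without animal data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    RNifti,
    png,
    tiff,
    car
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
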