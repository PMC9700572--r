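Package: annulusFD
Title: Box-Counting Fractal Dimension of the Aortic Annulus from Calibrated CT Slices
Version: 0.1.0
Authors@R:
    person("Core", "Lab", email = "corelab@example.org", role = c("aut", "cre"))
Description: Semi-automatic segmentation of the aortic annulus and left
    ventricular outflow tract (LVOT) border from calibrated cross-sectional
    CT-slice images, fixed-grid box-counting fractal dimension (FD) over a
    physical caliber range, conventional Euclidean annulus morphometry
    (area, circumference, diameters, eccentricity, non-tubularity), and a
    cohort statistics layer (Mann-Whitney U, Pearson correlation, ROC with
    Youden cutoff, Cronbach's alpha and absolute-agreement ICC). Includes a
    synthetic image and cohort generator with analytically known fractal
    dimensions so every pipeline stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    isoband,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
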