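Package: morphoreg
Title: Neuronal-Morphology-Driven Registration of Serial-Section Electron Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Registration of serial-section electron microscopy (ssEM) image
    stacks driven by a stochastic model of local neuronal morphology. Implements
    the spherical deformation model (Gaussian spherical-harmonic surfaces) for
    simulating adjacent-section contour pairs, a closed-form theory linking
    contour roundness to translation-registration accuracy, a Fourier-based
    roundness index for selecting stable round regions from watershed
    segmentations of membrane probability maps, dense gradient-descriptor flow
    matching between adjacent sections, simultaneous constrained adjustment of
    correspondence positions across the whole stack, and rigid moving-least-squares
    warping of each section. Ships a synthetic EM-like phantom generator with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, Rcpp, Matrix, pracma, EBImage, withr, jsonlite, yaml, tiff, png
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
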