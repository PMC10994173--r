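Package: tiltflow
Title: On-the-Fly Cryo-Electron Tomography Tilt-Series Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated processing of cryo-electron tomography tilt series as
    acquired: histogram-based removal of unusable tilt images, fiducial-free
    coarse (pair cross-correlation) and fine (patch tracking plus
    projection-model refinement) alignment, sample pre-tilt estimation from
    feature flow and robust plane fitting, strip-based defocus and
    astigmatism determination for tilted images, SIRT reconstruction with
    automatic thickness estimation, and export of IMOD, Ctfplotter and
    RELION compatible files. Includes a forward simulator that generates
    tilt series with known ground truth so every stage is testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    optparse
Config/testthat/edition: 3
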