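Package: gustaquant
Title: Quantification Pipelines for Taste Bud Imaging and Gustatory Physiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable, tested implementations of the image and signal
    quantification procedures used to compare taste-bud composition,
    innervation, and neurotransmitter signaling between mouse genotypes:
    confocal z-stack conditioning (rolling-ball background subtraction,
    median filtering, stack-histogram Otsu binarization), per-taste-bud
    volumetric measurements (innervation density, two-channel overlap
    fractions, quadrant-plane cell-profile counts), Gaussian-mixture
    intensity thresholding for ganglion-cell scoring, baseline-normalized
    extraction of integrated nerve and ratiometric calcium responses,
    bioluminescence calibration of ATP release, and the accompanying
    nonparametric and factorial statistics.  A synthetic-data module
    generates every input with known ground truth so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    mclust,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
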