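Package: psrdose
Title: Phase-Space-Ring Beam-Model Commissioning and Fluence-Map-Biased
    Monte Carlo Dose Calculation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for automatic commissioning of analytical linac photon
    beam models built from phase-space-ring (PSR) sub-sources, and for
    efficient Monte Carlo dose calculation of VMAT treatment plans.
    Commissioning reweights sub-source intensities by non-negative least
    squares against measured-style water-phantom depth-dose curves and
    lateral profiles, using a sub-source dose matrix tallied concurrently
    during a single transport pass. Plan dose calculation biases the
    control-point assignment of sampled source particles through per-pixel
    inverse cumulative fluence-map look-up tables, reducing the number of
    particles wasted under closed multi-leaf-collimator leaves. Includes a
    simplified deterministic kernel transport in water, dosimetric
    evaluation metrics (RMS and maximum dose differences,
    distance-to-agreement, output factors, 3D gamma index), MetaImage dose
    grid input/output, and synthetic-data generators for beams,
    measurements and toy VMAT arcs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
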