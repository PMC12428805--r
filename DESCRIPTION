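Package: coronaflow
Title: Coronal Microvascular Displacement Mapping for En-Face OCTA Image Pairs
Version: 0.1.0
Authors@R:
    person("Coronaflow", "Developers", email = "coronaflow@example.org", role = c("aut", "cre"))
Description: Quantifies in-plane (coronal) displacement of the retinal
    microvasculature between two en-face optical coherence tomography
    angiography (OCTA) acquisitions of the same eye. Implements the full
    measurement pipeline: grayscale conversion and local (tiled) histogram
    equalization, iterative rigid roto-translational alignment driven by a
    36x36 displacement grid with a 3% sum-of-squared-differences convergence
    rule, dense two-frame Farneback optical flow via quadratic polynomial
    expansion, and whole-image plus concentric circular region-of-interest
    displacement statistics in micrometers. Includes a synthetic angiogram
    generator with known ground-truth warps for validation, cohort-level
    statistics (paired tests, random-intercept linear mixed models with
    estimated marginal means, phenotype associations), vector-overlay and
    color-coded deformation rendering, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    jsonlite,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
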