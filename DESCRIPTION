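Package: fcsquant
Title: Single-Cell Protein Quantification by Fluorescence Correlation Spectroscopy
Version: 0.1.0
Authors@R:
    person("FCS", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for quantifying low-abundance
    proteins in single live cells by fluorescence correlation spectroscopy
    (FCS). Provides Brownian-dynamics photon-trace simulation in a 3D Gaussian
    confocal volume, direct and multi-tau autocorrelation, nonlinear
    least-squares fitting of one- and two-component 3D diffusion models with a
    triplet term (two-stage fit with a free then fixed structural parameter),
    quality-control filtering, per-cell averaging into molecule numbers,
    molecular brightness (counts per molecule), diffusion coefficients and
    bound/unbound fractions, population-level nonparametric and parametric
    comparisons, and rank-normalisation coupling of whole-cell intensity
    distributions to FCS molecule numbers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
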