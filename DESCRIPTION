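Package: ciaccess
Title: Zero-Point-Energy Accessibility of Conical-Intersection Seams and
    Nonadiabatic Decay of Peptide Chromophores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for rationalising conformer-specific nonradiative decay of
    UV-excited aromatic residues in small peptides. Builds harmonic
    normal-mode bases from Cartesian Hessians (Eckart-projected), classifies
    conical-intersection (CI) geometries as classically accessible per mode by
    comparing the harmonic mode energy with the zero-point energy, computes
    semiclassical (WKB) tunneling probabilities through per-mode barriers and
    their product, locates minimum-energy and minimum-distance CIs on pluggable
    potential-energy surfaces with a sequential penalty method, expands
    accessible CI seams by pair/triplet interpolation with zero-point-energy
    filtering, runs fewest-switches surface hopping on analytic two-state
    model surfaces, and converts seam-access probabilities into first-order
    rate and lifetime ratios. Ships a synthetic surrogate-surface generator
    with analytically known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    withr,
    ggplot2,
    generics,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
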