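Package: flatbottomr
Title: Flat-Bottom Restraints for Solvent Asymmetry Across Lipid Bilayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for setting up and validating single-bilayer molecular
    dynamics simulations that maintain distinct solvent compositions on the
    two sides of a lipid membrane using an inverted flat-bottom restraint at
    the periodic box edge. Provides the closed-form restraint potential and
    its derived quantities (barrier height, Boltzmann-weighted excluded
    width, extra-water correction), a Brownian-dynamics calibration analog
    for choosing the restraint half-width and force constant from
    plane-crossing statistics and density matching, byte-exact generation of
    GROMACS-style reference-coordinate files and position-restraint topology
    stanzas, a trajectory analysis suite for the standard membrane
    observables (number-density and water-dipole orientation profiles, area
    per lipid, phosphate-to-phosphate thickness, headgroup tilt, deuterium
    order parameters, center-of-mass drift, double-bilayer profile
    averaging), and deterministic synthetic-data generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
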