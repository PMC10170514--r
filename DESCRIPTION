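Package: hjdyn
Title: Holliday Junction Opening-Closing Dynamics Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the conformational dynamics of DNA
    Holliday junctions in molecular simulations. Builds pairwise
    Lennard-Jones tables from AMBER topologies and applies branch-point
    lambda-scaling and cation-phosphate pair overrides (the NBfix
    mechanism); computes stacking coordination-number collective
    variables with a rational switching function; classifies frames into
    the seven junction states (open, two stacked isomers, four
    half-closed intermediates) and counts transition pathways; provides
    a desk-scale well-tempered metadynamics and Hamiltonian
    replica-exchange sampler on analytic surfaces; reweights biased
    trajectories into two-dimensional free-energy surfaces and state
    free energies with block-bootstrap errors and a linear
    free-energy-versus-lambda fit; and computes ion-atmosphere
    statistics (radial distribution functions, ionic bridging incidence,
    junction-center ion counts, effective bulk concentration). A
    synthetic-data module generates ground-truth-annotated fixtures for
    every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
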