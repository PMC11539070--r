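Package: cosmoform
Title: Coformer Screening for Ternary Amorphous Solid Dispersions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A computational preformulation funnel for ternary amorphous
    solid dispersions of a drug, a cellulosic polymer, and a small-molecular
    coformer. Implements an open COSMO-RS-style statistical thermodynamics
    engine operating on sigma-profiles (segment pair interaction energies,
    self-consistent sigma-potential, pseudochemical potentials, activity
    coefficients, and excess mixing enthalpy by a Gibbs-Helmholtz finite
    difference), estimation of Hansen partial solubility parameters by
    in-silico solubility screening over a reference solvent set, coformer
    preselection through the overlap range of solubility parameter (ORSP),
    and mapping of candidates on the melting-point versus excess-enthalpy
    plane against a hot-melt-extrusion process temperature window.
    Ships a synthetic fixture generator with known ground truth so that
    every stage of the funnel is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, tools
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
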