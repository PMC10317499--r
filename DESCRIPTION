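Package: crceta
Title: Agonist Efficiency from Single-Channel Concentration-Response Curves
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts single-channel concentration-response curves (CRCs) of
    nicotinic acetylcholine receptors into agonist and mutant equilibrium
    constants, binding free energies, efficacy and efficiency (eta) under a
    two-site bind-and-gate activation model.  Includes Hill fitting of
    cluster open probabilities, closed-form inversion of CRC parameters to
    resting and open-state dissociation constants, voltage and
    background-mutation corrections of the unliganded gating constant,
    x-means classification of efficiency values, efficiency-plot and
    binding-energy-correlation regressions, dwell-time analysis of idealized
    interval lists (dead-time imposition, cluster segmentation,
    left-truncated exponential-mixture maximum likelihood), and exact
    stochastic simulation of the activation scheme for end-to-end
    validation against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
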