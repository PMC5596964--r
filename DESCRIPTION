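Package: foldkin
Title: Equilibrium and Stopped-Flow Kinetic Analysis of Protein Folding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing chemical-denaturation experiments on small
    proteins: two-state equilibrium unfolding fits with sloping baselines
    (linear extrapolation method), mono- and bi-exponential fitting of
    stopped-flow fluorescence relaxation traces with dead-time handling and
    information-criterion phase-count selection, two-branch chevron-plot
    fitting of observed relaxation rates, free-energy bookkeeping across
    kinetic phases, and classification of folding intermediates as on- or
    off-pathway. Includes a three-state (U-I-N) master-equation simulator
    that generates synthetic titrations, kinetic traces and chevron
    datasets for validation and power analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
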