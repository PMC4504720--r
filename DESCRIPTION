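Package: tetracross
Title: Tetrad Analysis of Meiotic Crossover Interference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of meiotic recombination from fluorescent-tagged-line
    (FTL) pollen tetrads, cytological chiasma counts, and calibrated axis
    immunosignal intensities. Classifies three-colour tetrads into joint
    parental-ditype/tetratype/non-parental-ditype states, estimates genetic
    map distances with the Perkins equation and delta-method standard errors,
    quantifies crossover interference via the interference ratio (with Z-test)
    and the coefficient of coincidence, tests per-cell chiasma counts against
    a Poisson expectation, and compares bead-normalised synapsed versus
    unsynapsed axis intensities with a paired t-test. A seeded meiosis
    simulator generates tetrad, chiasma, and intensity datasets from a
    stationary gamma-renewal crossover model on the four-chromatid bivalent
    with tunable interference strength and a non-interfering (Class II)
    pathway fraction, so every analysis stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
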