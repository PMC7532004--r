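Package: gabarod
Title: Resting-Open-Desensitized State Analysis of GABA-A Receptor Currents
    and Neurosteroid Modulation of Orthosteric Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing macroscopic GABA-A receptor currents in the
    framework of the three-state Resting-Open-Desensitized (ROD) equilibrium
    model. Converts peak and steady-state open probabilities into state
    occupancies, estimates the open/desensitized equilibrium constant Q and its
    modification by neurosteroids, and predicts the resulting enhancement of
    low-concentration orthosteric radioligand binding. Includes the curve fits
    used alongside the model (single-site binding isotherms, Hill modulation
    curves, mono-exponential binding time courses), current-trace metrics
    (open-probability normalization, percent desensitization, potentiation
    ratios), photolabeling-efficiency quantification from chromatographic
    areas, and a seeded synthetic-data generator implementing a three-site,
    state-dependent neurosteroid scheme for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
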