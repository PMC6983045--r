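Package: cosolvr
Title: Cosolvency Modeling of Drug Solubility in Binary Solvent Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the thermodynamic and model-based analysis of
    mole-fraction solubility measured on a temperature by solvent-composition
    grid in binary (cosolvent + water) systems. Computes ideal solubility from
    fusion properties and activity coefficients, apparent dissolution
    thermodynamics (van't Hoff/Gibbs analysis at the harmonic-mean
    temperature), enthalpy-entropy compensation, and fits five cosolvency
    models (van't Hoff, Apelblat, Yalkowsky-Roseman log-linear, Jouyban-Acree,
    and Jouyban-Acree-van't Hoff) with percent root-mean-square deviation
    goodness of fit. Ships the 6-phenylpyridazin-3(2H)-one (PPD) in
    DMSO + water solubility dataset as a worked fixture and includes a
    synthetic-surface generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
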