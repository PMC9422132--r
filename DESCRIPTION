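Package: csfosmosis
Title: Osmotic Water Transport Analysis for Cerebrospinal Fluid Secretion
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantitative analysis of cerebrospinal fluid (CSF) secretion by
    the choroid plexus: dye-dilution estimation of secretion rates from
    ventriculo-cisternal perfusion, derivation of the trans-epithelial
    osmotic water permeability from osmotic-challenge regression, microvillar
    morphometry and hydraulically equivalent channel geometry, a
    standing-gradient (Diamond-Bossert) boundary-value model of the
    inter-microvillar space, isotope-efflux and dose-response kinetics, and
    seeded synthetic-data generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
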