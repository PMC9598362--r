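Package: icecal
Title: Latent-Heat Release During Freezing of Solute-Laden Aqueous Solutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for modelling and measuring the latent heat released when
    solute-laden aqueous solutions (phosphate-buffered saline, glycerol media
    and similar cryopreservation solutions) freeze under constant cooling.
    Implements the water-NaCl binary phase diagram (freezing-point depression
    and lever-rule release fractions), a separable temperature-time
    crystallization model with Avrami kinetics and its two-stage least-squares
    fitting pipeline, processing of differential scanning calorimetry (DSC)
    thermograms (nucleation-exotherm detection, linear and sigmoidal baseline
    construction, enthalpy integration, cumulative release curves), a reduced
    moving-boundary solute-diffusion model of freezing in a small container
    solved with a semi-implicit finite-difference scheme on a mapped fixed
    domain, and a synthetic-data generator so that every pipeline stage can be
    exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
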