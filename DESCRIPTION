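Package: thermoshift
Title: Thermophilisation of Plant Communities and Notional Elevation Shifts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify thermophilisation of bryophyte and vascular
    plant communities from permanent-plot resurvey data. Computes community
    temperature indices (CTI) from ordinal temperature indicator values,
    per-plot thermophilisation rates, the notional elevation shift (NES,
    metres per decade) obtained by normalising CTI trends by the elevational
    CTI lapse, and the expected isotherm shift implied by an observed warming
    rate. Fits the associated mixed-effects model families (CTI trend models
    with cluster-bootstrap intervals, NES models with a power variance
    function, Poisson models for temperature-affinity species counts, and
    life-strategy contrasts) and ships a synthetic-data generator that
    emulates the plot-by-survey structure of a national biodiversity
    monitoring network so the whole pipeline can be exercised and validated
    without access to the original field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    lme4,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
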