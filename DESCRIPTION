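Package: cesdem
Title: Demographic Drivers of Annual Population Change from Constant Effort Ringing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking annual adult survival and productivity to annual
    population change of songbirds captured at constant effort ringing sites
    (CES). Provides the capture-record data model and site/species selection
    filters, a Cormack-Jolly-Seber mark-recapture likelihood with a transience
    mixture and site-level recapture probabilities, quasi-binomial productivity
    and quasi-Poisson adult-abundance annual indices, inverse-variance weighted
    per-population growth-rate regressions, and weighted linear mixed
    meta-models relating the demographic coefficients to migratory strategy,
    breeding habitat and mean breeding-season temperature. A multi-scheme
    synthetic capture-data generator with known demographic truth supports
    parameter-recovery studies end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
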