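Package: lclink
Title: Probabilistic Record Linkage with Loglinear Latent Class Models
Version: 0.1.0
Authors@R:
    person("Maintainer", "lclink", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for probabilistic record linkage and de-duplication with
    the Fellegi-Sunter two-class latent mixture and its loglinear extension
    that allows conditional dependence between comparison fields. Provides
    blocking and agreement-pattern tabulation for flat record files,
    maximum-likelihood and EM fitting of loglinear latent class models with
    pairwise within-class interactions, a correlation-residual diagnostic for
    detecting conditional dependence, an automated stepwise model-building
    procedure driven by BIC, match scoring and record-pair classification,
    and a seeded synthetic-data generator for calibration and parameter
    recovery studies. A command-line interface ties the steps into a
    reproducible pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
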