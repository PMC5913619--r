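Package: negctrlbias
Title: Bias of Negative-Control Exposure Analyses Under Measurement Error
    and Unmeasured Confounding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the bias of ordinary least squares estimates in
    negative-control exposure studies when the exposure and/or the negative
    control are measured with error in the presence of an unmeasured
    confounder. Implements the closed-form asymptotic bias of the OLS
    estimator from the moment matrices of the structural model, generates
    bias-versus-confounding curves over grids of measurement-error
    configurations (intraclass correlation coefficients for continuous
    variables, symmetric misclassification for binary variables), and runs
    seeded Monte Carlo simulation studies that reproduce the bias tables for
    dichotomized exposures, including validation of the analytic formula
    against simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
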