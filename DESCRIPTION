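Package: loamci
Title: Limits of Agreement with the Mean for Multiple Observers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and inference for limits of agreement with the mean
    (LOAM) when a continuous quantity is measured by several observers, with
    optional replicate measurements per observer. Measurements are modelled by
    an additive two-way random effects model with crossed subject and observer
    effects; variance components are estimated by closed-form ANOVA moment
    estimators. Provides the LOAM point estimate with an asymmetric
    Graybill-Wang confidence interval, exact and delta-method confidence
    intervals for the subject, observer and residual standard deviations, the
    intraclass correlation ICC(A,1) with an approximate confidence interval,
    sample-size planning for the number of observers, agreement plots, a
    parametric simulator, and a Monte Carlo coverage harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, grDevices, utils, jsonlite
Suggests: testthat (>= 3.0.0), lme4, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
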