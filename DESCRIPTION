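Package: zonesae
Title: Hierarchical Bayes Small Area Estimation of Zone-Level Proportions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Area-level small area estimation for a binary indicator
    (community-based health insurance enrolment) at administrative levels
    below the design level of a household survey.  Implements design-based
    direct estimation with continuity correction, generalized variance
    function (GVF) smoothing of design variances, hierarchical-Bayes
    Fay-Herriot model fitting under identity, log and logit linking models
    via a Metropolis-within-Gibbs sampler, DIC model comparison,
    posterior-predictive estimation for non-sampled areas, and the standard
    diagnostic battery (bias-diagnostic regression, residual normality,
    CV and efficiency-gain comparison).  Ships a synthetic-data generator
    emulating the zone-level structure of the 2019 Ethiopia
    Mini-Demographic and Health Survey combined with 2007 census auxiliary
    covariates, so the full pipeline is testable without restricted
    microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
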