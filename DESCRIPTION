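Package: betagbtm
Title: Group-Based Trajectory Models for Beta-Distributed Longitudinal Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood estimation of group-based trajectory models
    (finite mixtures of latent trajectory classes) for bounded continuous
    longitudinal outcomes using the mean-precision parameterization of the
    beta distribution. Each latent group follows its own polynomial mean
    trajectory on a link scale with a group-specific precision parameter;
    mixing proportions follow a multinomial logit. Supports an optional
    logistic dropout sub-model for non-random attrition, multi-start
    quasi-Newton optimization with standard errors from the observed
    information matrix, AIC/BIC model selection over the number of groups,
    backward pruning of polynomial orders by Wald tests, boundary-value
    adjustment for exact 0/1 observations, posterior classification
    diagnostics, and a synthetic-panel generator for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
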