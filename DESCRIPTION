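Package: habfr
Title: Habitat-Structured Functional Response Models for Depleted Feeding Trials
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood estimation of predator functional responses
    from non-replacement feeding trials, where prey density declines during
    the trial. Implements the Rogers random-predator (depletion-corrected)
    type II likelihood via the Lambert W function, the generalized type
    II/III response with shape parameter q fitted by simulating the
    within-trial prey decline, a factorial suite of 32 models that link the
    attack rate/handling time ('Holling') or maximum feeding rate/
    half-saturation density ('Real') parameterizations to habitat-complexity
    predictors, AIC/BIC model selection, profile-likelihood confidence
    intervals, bootstrap prediction bands, and a synthetic feeding-trial
    generator with an event-based stochastic depletion oracle for testing
    the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
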