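Package: trajmix
Title: Latent Growth Mixture Trajectories of Peak-Age Neurocognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling longitudinal neurocognitive trajectories in
    cohorts of older adults ageing with HIV. Implements regression-based
    neuropsychological norming with "peak-age" (age-25) substitution and
    practice-effect correction, SuperAger / cognitively-normal / impaired
    baseline classification via the global deficit score, a 39-item
    deficit-accumulation physiologic reserve index, a growth mixture model
    engine (EM with full-information maximum likelihood for missing visits,
    multi-start, AIC/BIC/ssBIC/entropy, Lo-Mendell-Rubin and bootstrap
    likelihood-ratio class enumeration), three-step covariate analysis by
    multinomial logistic regression, and a synthetic cohort generator that
    emulates the longitudinal structure of a multi-visit observational
    neuroHIV study for testing and power work.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
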