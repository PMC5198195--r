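Package: cageload
Title: Stochastic Cage-Population Dynamics and Fitness-Load Inference for
    Sterile-Male Transgenes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Day-by-day stochastic simulation of overlapping-generation
    laboratory cage populations of Anopheles gambiae carrying a hemizygous
    male-sterilizing transgene, with Weibull adult survival discretized to
    daily hazards, genotype-specific pupation delays, and weekly egg harvests
    restocking a fixed adult cohort.  Provides an approximate Bayesian
    computation (ABC) rejection sampler that infers additional fitness loads
    on egg-batch size and adult longevity from observed weekly
    transgene-proportion time series, a synthetic cage-experiment generator
    with binomial larval screening, and ensemble quantile-band summaries for
    comparing observations with model predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
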