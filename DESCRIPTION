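Package: srcontrol
Title: Statistical Risk Control Charts for Occupational Accident Surveillance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Dynamic surveillance of an occupational-accident rate from
    precursor observations. Provides Bayesian updating of a per-interval
    event rate under five likelihood/prior model pairs (Poisson, exponential
    and Weibull likelihoods with gamma or normal priors), a seeded
    random-walk Metropolis-Hastings sampler with acceptance-rate tuning for
    the non-conjugate models, control charts with prior-target or posterior
    center lines and k-sigma limits that flag out-of-limits intervals, and a
    hidden-Markov analysis of mitigative safety barriers and injury end
    states (Baum-Welch fitting over a rolling observation window,
    steady-state occupations, expected visits, and mean first-passage
    times). A bow-tie scenario model routes observed initiation causes and
    barrier failures into per-interval counts, and a synthetic generator
    simulates incident streams and barrier sequences with known parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
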