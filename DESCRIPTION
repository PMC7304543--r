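Package: gbmwave
Title: Traveling-Wave Growth Modelling and Parameter Estimation for Glioblastoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements a two-population (proliferating/quiescent) cross-diffusion
    reaction-diffusion model of glioblastoma multiforme growth with explicit,
    growth-factor-dependent birth and death responses drawn from the beta-CDF
    family. Provides the phase-plane (Canosa) approximation of the traveling-wave
    profile, dimensionless width integrals for the contrast-enhancing rim and the
    edema, and two protocols that invert three MRI-derived tumor radii (necrotic
    core, enhancing rim, edema extent) into patient-specific diffusion,
    proliferation, and death rates. A method-of-lines solver for the full
    cross-diffusion system validates the approximation, and a synthetic-patient
    generator forward-models observations from known parameters for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
LinkingTo:
    Rcpp
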