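Package: ggfisher
Title: Fisher Information and Study Design for the Gamma-Gompertz Frailty Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and evaluating studies of old-age mortality
    deceleration under the gamma-Gompertz frailty model with left-truncated
    ages at death. Provides the distribution (hazard, survival, density,
    quantiles), analytic score and Hessian of the log-density with exact
    sigma^2 = 0 boundary limits, the expected Fisher information per
    left-truncated observation by adaptive quadrature, optimal-design
    information measures (D-, A-, E- and D_A-optimality, scaled by survival),
    sample-size translation across truncation ages, maximum-likelihood fitting
    with boundary-aware optimization, the likelihood ratio test for a zero
    frailty variance with its 50:50 chi-squared mixture null, an asymptotic
    power approximation, and a cohort simulator with a replication-study
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), pracma, jsonlite, optparse, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
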