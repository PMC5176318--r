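Package: hdsde
Title: Mixed-Effects Stochastic Differential Equation Height-Diameter Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tree height distributions conditional on breast-height diameter,
    modelled by five diffusion processes of the Ornstein-Uhlenbeck family
    (Vasicek, three- and four-parameter Gompertz, Bertalanffy and Gamma) with
    a plot-level random effect on the asymptote parameter. Provides the
    closed-form transition laws (density, mean, variance, quantiles), exact
    simulation of forest-inventory style datasets, fixed- and mixed-effects
    maximum likelihood estimation via the Laplace approximation with
    observed-information standard errors, closed-form calibration
    (localization) of the random effect from a sub-sample of trees,
    stochastic height prediction, derived stand attributes (slenderness
    ratio, mean stem volume, coefficients of variation, quantile curves) and
    model comparison by Kullback-Leibler information and prediction fit
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
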