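Package: multimorb
Title: Age-Specific Multimorbidity from Cross-Sectional Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how pairs of chronic diseases co-occur across age in
    cross-sectional health survey data. Disease-pair status (none, only A,
    only B, both) is modelled as a smooth function of age with penalized
    multinomial B-spline (P-spline) regression; the smoothing parameter is
    chosen by AIC or BIC. From the fitted category probabilities the package
    derives age-specific joint prevalence, observed-minus-expected and
    observed/expected co-occurrence, with pointwise Monte Carlo confidence
    intervals obtained by resampling regression coefficients from their
    asymptotic multivariate normal distribution. A synthetic survey
    generator with known marginal prevalence curves and known age-varying
    pairwise odds ratios (Plackett construction) provides ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    nnet,
    optparse,
    splines,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
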