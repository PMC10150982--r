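Package: songdev
Title: Latent-Space Models of Juvenile Birdsong Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing juvenile zebra finch song development in a
    low-dimensional acoustic latent space. Provides a synthetic-data generator
    with known developmental and circadian structure, an audio-to-spectrogram
    PCA feature path, a neural "predicted age" maturity regressor with total
    and within-day permutation controls, a time-varying multivariate Gaussian
    density network over (age, time-of-day) covariates trained by negative
    log-likelihood, differential-entropy trajectories with mixed-effects
    circadian analysis, counterfactual entropy-clamped developmental
    simulations, and quantile-wise overnight maturity-shift statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    lmerTest,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    arrow
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
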