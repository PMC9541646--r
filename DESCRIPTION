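Package: sadglmm
Title: Dynamic Species Abundance Distributions as Poisson Lognormal Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits dynamic species abundance distributions to community count
    data using intercept-only Poisson generalized linear mixed models with
    ecologically interpretable random effects: among-species heterogeneity,
    species-specific and common environmental responses with
    Ornstein-Uhlenbeck (temporal) or exponential-decay (spatial) correlation,
    observation-level overdispersion and uncorrelated sampling-unit noise.
    Marginal likelihoods are maximized via a sparse Laplace approximation.
    Variance components transform to population-dynamic parameters of the
    underlying Gompertz model (growth-rate heterogeneity, environmental
    variances, strength of density regulation, log carrying capacity), and
    community similarity in relative and mean log abundance is expressed as
    spatio-temporal correlation functions. Includes a multispecies Gompertz
    community simulator, parametric-bootstrap uncertainty quantification,
    readers for long-format community tables including the BioTIME CSV
    dialect, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    geosphere,
    optparse
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    withr
Config/testthat/edition: 3
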