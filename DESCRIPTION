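Package: nldcm
Title: Linear and Non-Linear Dynamic Causal Modelling of Auditory BOLD Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inversion of bilinear and non-linear dynamic causal
    models (DCM) of BOLD time series for small cortical networks, with a
    balloon-Windkessel haemodynamic forward model, variational-Laplace model
    inversion, random-effects Bayesian model selection (Dirichlet posterior
    over model frequencies with exceedance probabilities), and group-level
    connection statistics (one-sample t-tests with Bonferroni control and
    posterior-probability pruning). Includes a synthetic-data generator for
    sparse-sampling auditory paradigms and a two-stage group analysis
    pipeline for a four-region auditory network (bilateral Heschl's gyrus
    and superior temporal gyrus).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    Matrix,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
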