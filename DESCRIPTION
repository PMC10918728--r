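Package: misclassSDM
Title: Multi-Species Distribution Models with a Heterogeneous
    Classification Process
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint Bayesian modelling of a relative-abundance ecological
    process and a covariate-dependent (heterogeneous) species
    classification process for individual-level occurrence records that
    are prone to taxonomic misclassification. The classification
    confusion matrix is modelled row-wise with multiple multinomial
    generalised linear models, with spike-and-slab selection of the
    classification covariates, Dirichlet-conjugate homogeneous variants,
    and a non-parametric alternative that weights reported-state
    intensities by machine-learning prediction scores. Fitting is by
    Metropolis-within-Gibbs with latent true-state imputation; tools are
    included to simulate study designs, predict withheld true-state
    identities, and score predictions by accuracy, precision and recall.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
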