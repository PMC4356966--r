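Package: isinglr
Title: Bayesian Estimation of Low-Rank Ising Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Full-data-information Bayesian estimation of Ising networks whose
    connectivity matrix is well approximated by a low-rank (Eckart-Young)
    truncation.  The package implements the latent-variable (multidimensional
    item response theory) representation of the Ising model, a Gibbs scheme
    that alternates exact multivariate-normal draws of the latent variables
    with order-statistic independence Metropolis-Hastings updates of the main
    effects and loadings, posterior predictive checks on the sufficient
    statistic, exact enumeration oracles for small networks, and synthetic
    generators for nearest-neighbour lattice and dense low-rank networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
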