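Package: jacrecon
Title: Jacobian Reconstruction from Stationary Fluctuations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Closed-form reconstruction of the Jacobian matrix of a
    dynamical system from the covariance of its stationary fluctuations.
    The Lyapunov relation J Gamma + Gamma J' = -2 D links the Jacobian J
    to the fluctuation covariance Gamma and the noise fluctuation matrix
    D; vectorising this relation with Kronecker products and a
    commutation matrix, and augmenting it with structural zeros implied
    by network topology, yields a constrained linear least-squares
    problem with an explicit solution. The package provides the
    reconstruction itself, derivation of structural-zero patterns from
    spatial networks and multilayer metacommunities, a forward Lyapunov
    solver and master-stability spectra as exact oracles, stochastic
    (Euler-Maruyama) simulation of linear and Rosenzweig-MacArthur
    metacommunity models, and sliding-window estimation of the leading
    Jacobian eigenvalue as an early warning signal for bifurcations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
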