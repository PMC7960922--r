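Package: heatrewire
Title: Adaptive Rewiring of Weighted Networks by Heat-Kernel Diffusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates structural plasticity in weighted undirected networks
    by adaptive rewiring: at every step the connection carrying the least
    heat diffusion at a pivot node is pruned and a connection is added to
    the non-neighbour receiving the most diffusion, where diffusion is the
    graph heat kernel exp(-tau * L) of the normalized Laplacian. Provides
    generators for connected random networks with normal or lognormal edge
    weights, a fast compiled rewiring engine, weighted modularity and
    multilevel community detection, degree-outlier statistics against a
    Poisson baseline, and the analysis battery around the modular-to-
    centralized phase transition: rewiring-interval sweeps, inflection-point
    detection, perturbation distributions, initial-versus-final modularity
    correlation, the two-stage specificity/robustness experiment, and
    bootstrap R-squared estimates of rewiring flexibility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
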