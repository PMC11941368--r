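Package: bridgemc
Title: Monte Carlo Integration of Fokker-Planck and Hamilton-Jacobi-Bellman
    Equations for Stochastic Optimal Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the numerical study of optimal control problems in
    stochastic thermodynamics. Solves Fokker-Planck equations driven by
    time-dependent mechanical potentials pointwise by Girsanov-reweighted
    Monte Carlo averages over auxiliary backward diffusions, for both
    overdamped (Langevin-Smoluchowski) and underdamped (Langevin-Kramers)
    dynamics. Estimates gradients of Hamilton-Jacobi-Bellman value functions
    with the Bismut-Elworthy-Li formula, including the degenerate
    (hypoelliptic) underdamped case via explicitly constructed variational
    fields. Includes a half-bridge iteration for the overdamped Schroedinger
    bridge (Foellmer drift), and a gradient-descent learner that couples the
    two Monte Carlo primitives to train a parametrized control protocol
    against assigned boundary marginals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    tidyr,
    generics,
    ggplot2,
    parallel,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
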