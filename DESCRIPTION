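Package: estrodyn
Title: Estrogen-Modulated Breast Tumor-Immune Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic population models of breast-cancer dynamics:
    a three-compartment host/tumor/immune competition system of
    Lotka-Volterra type and a four-compartment extension with a constant
    estrogen source. Provides closed-form and numerical equilibria with
    feasibility conditions, local stability classification by Jacobian
    eigenvalues with Routh-Hurwitz and trace/determinant diagnostics,
    Castillo-Chavez global-stability checks of the tumor-free state,
    adaptive Runge-Kutta trajectory simulation with outcome
    classification, estrogen-dose sweeps with stability-boundary
    bisection, and synthetic-data generation with least-squares
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
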