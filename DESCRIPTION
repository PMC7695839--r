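Package: ecostab
Title: Dispersal-Induced Instability in Complex Ecosystems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Random-matrix tools for studying the stability of large model
    ecosystems with trophic structure and diffusive dispersal. Provides a
    generator for block-structured correlated random community matrices,
    analytic solvers for the bulk eigenvalue boundary and outlier eigenvalues
    of the wavenumber-dependent stability matrix, dispersion relations and
    stability phase diagrams (including the May complexity bound as a limiting
    case), and a nonlinear Levin-Segel-type reaction-diffusion simulator in
    which dispersal-induced (Turing-type) instability can be observed
    dynamically.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    yaml,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
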