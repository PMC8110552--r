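Package: stripesim
Title: Lattice Models of Pigment-Cell Pattern Formation in Zebrafish Skin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic and deterministic simulation of lattice-based
    models of zebrafish skin patterning, in which immobile melanophores and
    xanthophores interact through short-range competition and long-range
    survival or promotion feedback. Provides a rejection kinetic Monte
    Carlo engine on static and growing periodic lattices (with in silico
    ablation), the corresponding deterministic mean-field equations in one
    and two dimensions, the continuum cross-diffusion approximation with a
    full linear stability analysis of the Turing bifurcation, and spectral
    pattern metrics (dominant wavelength, stripe orientation, amplitude,
    classification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
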