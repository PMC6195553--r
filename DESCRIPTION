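Package: geldiff
Title: Binding-Enhanced Particle Diffusion in Reversibly Crosslinked Star-Polymer Gels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid Brownian-dynamics/Gillespie simulation of a tracer particle
    diffusing through a two- or three-dimensional gel of star-shaped polymers
    held together by reversible crosslinks.  Crosslink binding sites follow a
    three-state (free/crosslinked/bound) equilibrium kinetics model with
    Arrhenius transition rates derived from state and transition-state
    energies, so that particles that bind competitively to the crosslink sites
    can catalyse crosslink exchange and thereby enhance their own diffusion.
    Provides closed-form equilibrium results for the site model, gel builders
    (lattice gels, shell geometries, tracer placement), an overdamped Langevin
    integrator coupled to an overlap-gated Gillespie bond-kinetics engine,
    and trajectory analysis tools (mean-squared displacement, diffusion
    constants, parameter sweeps, filtering demonstrations, crosslink-lifetime
    statistics) with ggplot2 visualisations and broom-style tidiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
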