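Package: poromca
Title: Particle-Based Poroelastic Simulation of Shockwave Treatment of the Knee
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A movable-cellular-automata style bonded-particle simulator for
    poroelastic biological tissues. Solids are ensembles of equal-sized
    automata on an FCC lattice whose many-body elastic interactions reproduce
    isotropic linear elasticity; Biot pore-pressure coupling and Darcy
    inter-particle fluid exchange describe the two-phase response of bone,
    cartilage, meniscus and capsule tissues. Includes energy-flux-density
    calibrated shock-pulse loading, mechanobiological regeneration criteria
    (compressive stress, distortional strain, pore fluid pressure windows),
    closed-form verification oracles (confined moduli, Skempton response,
    Terzaghi consolidation), a procedural layered knee-joint analog, and
    drivers for mesh-convergence, compression-validation and energy-flux
    density sweep studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
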