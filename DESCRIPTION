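Package: corrugo
Title: Agent-Based Simulation of Biofilm Growth in Corrugated Microwells
Version: 0.1.0
Authors@R: person("Corrugo", "Developers", email = "corrugo@example.org",
    role = c("aut", "cre"))
Description: A two-dimensional agent-based model of bacterial biofilm growth
    in quasi-2D microwells whose bottom surface carries a sinusoidal
    corrugation. Rod-shaped cells are represented as growing spherocylinders
    with Hertzian-like contact repulsion, linear wall repulsion, breakable
    cell-wall adhesion springs, and overdamped (Stokes-friction) dynamics;
    biomass leaving through the open top of the well is removed. The package
    tracks heritable neutral genotypes and two-strain fitness mixtures, and
    provides the population-genetic summaries used to study how substrate
    geometry shapes clonal dynamics: clone censuses, sector transects and
    boundary densities, heterozygosity, founder-survival densities,
    coarse-grained velocity fields with continuity-equation growth rates,
    and logistic-replicator fitness estimation from strain-fraction time
    series. Synthetic fixture generators and plain-text snapshot formats
    support fully reproducible in-silico experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
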