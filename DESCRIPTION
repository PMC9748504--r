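Package: swarmob
Title: Collective Motion of Self-Propelled Agents Among Tethered Obstacles
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-level model of collective motion in an obstacle-laden
    environment. Provides a stochastic agent-based simulator of Vicsek-type
    self-propelled particles interacting with spring-tethered obstacles on
    the periodic unit square, and the matching continuum hydrodynamic
    equations for the agent density and mean orientation with a differential
    closure for the obstacle density. Includes the linear-stability toolkit
    (dispersion relations, Routh-Hurwitz conditions for complex-coefficient
    polynomials, the bifurcation parameter, predicted pattern sizes and
    growth rates), Fourier-based pattern-size measurement, and a pipeline to
    compare discrete point clouds with continuum densities via
    particle-in-cell density estimation, optimal grid selection, histogram
    signatures and the earth mover's distance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
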