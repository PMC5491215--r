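Package: netdendro
Title: Spatial Point Pattern Analysis on 3D Dendritic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical analysis of point patterns that live on linear
    networks embedded in 3D, with dendritic trees and their spines as the
    motivating case. Provides exact shortest-path geometry on continuum
    trees (distances, the exact-distance count m(u,t), circumradius),
    network K functions with the geometric correction that makes them
    comparable across networks, inhomogeneous Poisson intensity models
    with a log-quadratic dependence on distance to the root, kernel
    intensity-vs-covariate estimation, the Kolmogorov-Smirnov CDF
    covariate test, Monte Carlo global envelope tests, and a studentized
    permutation test for replicated grouped patterns. Includes SWC
    morphology I/O, a synthetic dendrite generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
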