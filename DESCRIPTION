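Package: troutsim
Title: Individual-Based Aquaculture Simulator Coupling Fish Schooling
    Behavior and Dynamic Energy Budget Growth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates rearing of rainbow trout (Oncorhynchus mykiss) in a
    circular tank by coupling a Boids-style schooling and feeding behavior
    model with a dynamic energy budget (DEB) growth model. Each simulated
    day consists of a short behavioral episode in which feed pellets are
    released and individual fish encounter and ingest them, followed by a
    Runge-Kutta integration of per-individual gut content, reserve energy
    and structural volume. Includes feeding-schedule handling, feeding-level
    sensitivity analysis, feed conversion ratio summaries and error metrics
    against reference growth series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
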