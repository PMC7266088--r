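Package: xylotrait
Title: Tracheid-Level Wood Anatomical Traits, Their Drivers and Inter-Annual Stability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives ring-level wood anatomical traits (ring and earlywood/latewood
    widths, cell counts and density, cell wall thicknesses, Mork's index, relative
    wood density, hydraulic diameter and theoretical Poiseuille conductivity of
    elliptical conduits, cell wall reinforcement index) from per-cell tracheid
    measurement tables of conifer tree rings, and analyses their variation with a
    chain of year-wise principal component analyses, backward likelihood-ratio
    model selection against tree height, age and plot, Mantel tests on geographic
    distance, Procrustes tests of inter-annual score stability, and a coefficient
    of variation based trait-stability ranking. Includes a synthetic tracheidogram
    generator emulating a three-plot Norway spruce stand for end-to-end testing
    and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
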