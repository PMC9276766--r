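Package: tissellate
Title: Simulation and Mechanical Analysis of Colliding Epithelial Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design tool for tissue tessellations self-assembled from
    colliding expanding epithelia, together with the collision-mechanics
    analysis used to interpret such experiments. Tissues are seeded as
    geometric footprints, expand with a uniform normal edge speed, and pin
    where they meet; the package predicts the resulting boundary shapes and
    final tessellations, extracts and quantifies tissue-tissue boundaries,
    builds kymographs of velocity and cell density from PIV-style field
    data, locates centers of expansion, and infers the tissue
    pressure-density relation and bulk modulus from boundary motion down
    cell-density gradients. A synthetic-data generator emulates collision
    assays with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
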