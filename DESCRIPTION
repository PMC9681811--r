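Package: minicol
Title: Spatial Point-Pattern and Allometric Analysis of Cortical Minicolumn Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the spatial organization of radial myelinated fiber
    bundles (anatomical minicolumns) in tangential sections of primary visual
    cortex. Provides seeded generators for the point-pattern morphologies the
    analysis assumes (Poisson, hexagonal lattice, Matern hard-core, banded
    strings, linear density gradients) and for skewed inter-bundle distance
    sequences; second-order and nearest-neighbour regularity statistics
    (Ripley's K with translation and border corrections, the nearest-neighbour
    distance distribution G, the Clark-Evans ratio); Gaussian kernel intensity
    mapping with likelihood cross-validated bandwidth selection; distributional
    and sequential-group analysis of inter-bundle distance sequences; and the
    species-level allometric estimators linking total minicolumn number in V-1
    to visual acuity, including a packaged cross-species measurement table.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    e1071,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
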