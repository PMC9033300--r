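Package: gastrukit
Title: Quantitative Image Analysis of Gastruloid Polarization, Cell
    Neighborhoods, Tissue Flow, and Junction Tension
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying symmetry breaking in stem-cell
    aggregates (gastruloids) from microscopy data. Provides shape
    morphometry of binary aggregate masks (inertia-tensor elongation and
    elliptic Fourier descriptors with an area-convergence rule for the
    harmonic order), a fluorescence polarization statistic based on
    two-half intensity contrast under angular scanning, pruned Delaunay
    neighborhood graphs over labeled cell centroids with connected-
    component and homotypic-neighborhood statistics and radial
    population profiles, coarse-grained tissue velocity fields from
    dye-channel time-lapses (bright-object prefiltering, rigid
    registration by phase correlation, pyramidal Lucas-Kanade optic
    flow), and relative interfacial tension inference from junction
    contact angles. A seeded synthetic-data generator emulates each
    class of input so that every stage of the pipeline can be validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    deldir,
    igraph,
    isoband,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
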