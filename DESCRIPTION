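Package: molcart
Title: Molecular Cartography of Protein Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps triangulated 3-D molecular surfaces onto the plane and
    quantifies how faithful the flattening is.  Reads MSMS vertex/face
    surfaces, splits enclosed surfaces into open half-sections, embeds
    sections in 2-D by principal component analysis, classical
    multidimensional scaling, Sammon mapping, Isomap on mesh-edge
    geodesics, landmark Isomap, stochastic neighbor embedding, or an
    equal-area sinusoidal projection, and scores each map by the Pearson
    correlation of matched triangle areas and the Tanimoto similarity of
    k-nearest-neighbor connectivity.  Maps can be enriched with
    Kyte-Doolittle hydrophobicity, a screened-Coulomb electrostatic
    potential (or an imported potential grid), and discrete mean
    curvature, rasterized into multi-channel images, rigidly registered
    by normalized cross-correlation, and texture-mapped back onto the
    3-D surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    Matrix,
    bio3d,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
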