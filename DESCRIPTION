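Package: protshape
Title: Salient Shape-Index Similarity Analysis for Protein Surface Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Shape similarity analysis for three-dimensional protein surface
    models represented as triangle meshes. Estimates discrete Gaussian, mean
    and principal curvatures per vertex, derives the shape index (SI) and a
    salient geometric feature (SGF) field, condenses both fields into a K x K
    feature-matrix descriptor via one-dimensional K-means, and scores pairs of
    models with a matrix-extended grey relation degree in (0, 1]. Includes
    mesh input/output for OFF, PLY and OBJ, deterministic synthetic mesh
    generators with analytic curvature oracles, batch all-versus-all
    comparison, nearest-model search, average-linkage clustering with Newick
    export, and a scriptable command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    ape,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
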