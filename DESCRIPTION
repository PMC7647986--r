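Package: hingenet
Title: Gyral Hinge Detection and Hub Analysis of Cortical Structural
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Identify three-hinge gyral junctions on triangulated cortical
    surfaces via watershed crest-line extraction, parcellate surfaces into
    equal-area patches, build patch-level structural connectomes from
    streamline endpoints, compute weighted nodal graph metrics (degree,
    strength, betweenness, local efficiency, Onnela clustering,
    participation coefficient), run s-core and nodal-strength
    decompositions with folding-class ratio curves, and compare folding
    classes with label-permutation statistics and dictionary-learning
    functional involvement counts. Includes fully seeded synthetic
    generators: folded surfaces with planted ridge junctions, cohorts of
    modular weighted networks with planted hubs, streamline sets with
    known endpoint counts, and sparse-coded signal matrices.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
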