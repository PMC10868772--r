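Package: leafmapper
Title: Topological Data Analysis of Leaf-Shape Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Landmark-based geometric morphometrics and topological data
    analysis of heteroblastic leaf series on vining plants. Reads per-leaf
    2-D landmark tables with vine and node metadata, assigns relative node
    (heteroblasty) positions, superimposes shapes by generalized Procrustes
    analysis, builds PCA and LDA morphospaces, and constructs Mapper graphs
    under PC1 and heteroblasty lens functions using the correlation distance
    and density-based preimage clustering. Graph diagnostics (cycle rank,
    path-likeness, spine monotonicity) distinguish a conserved central-spine
    developmental program from branch-and-rejoin deviations, and a seeded
    synthetic leaf-series generator makes every stage testable without the
    original data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
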