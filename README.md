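# leafmapper

Topological data analysis of leaf-shape trajectories along vining shoots.

Leaves on a vine vary for confounded reasons: *heteroblasty* (the
developmental program changes from node to node along the shoot) and
*ontogeny* (each leaf is itself still developing, dramatically so near the
growing tip), on top of species differences. Classical ordination of
landmark data — PCA scatter, discriminant axes — summarises where leaves
sit in shape space but hides whether different species follow the *same
trajectory* through it. `leafmapper` implements the Mapper algorithm for
exactly this question: it turns a cloud of flattened landmark vectors into
a graph whose spine-and-branch structure shows whether a developmental
program is shared or diverges mid-series, for landmark datasets of the
grapevine (15 landmarks per leaf) and maracuyá (21 landmarks) type.

## The method in brief

Each leaf is an ordered set of n 2-D landmarks, flattened to a vector
`(x1, y1, ..., xn, yn)` — 30 numbers for a grapevine leaf. Distances
between leaves use the correlation distance `d = 1 − r` (Pearson's r of
the two vectors). A **lens** `f : X → ℝ` assigns each leaf a real value —
either its PC1 score or its **heteroblasty value**: relative node position
in [0, 1], 0 at the growing tip, 1 at the shoot base. The lens range is
covered by overlapping closed intervals; each interval's preimage is
clustered with DBSCAN on the correlation distances; the **Mapper graph**
is the nerve of that clustering — one vertex per cluster, an edge wherever
two clusters share a leaf. A conserved program appears as a path-like
central spine whose vertex mean-lens values ascend monotonically; a
morphotype with its own mid-series program branches off the spine and
rejoins it (a cycle: first Betti number `b1 = |E| − |V| + C ≥ 1` — the
"reverse hourglass" signature).

Around that core the package provides the standard morphometric stages:
generalized Procrustes superimposition, shared-landmark subsetting across
schemes, midline reflection completion of half-digitized leaves, PCA with
inverse-transform morphospace reconstruction, four-group (genus ×
shoot-position) linear discriminant analysis, graph diagnostics, and
"subway map" primary-structure extraction with mean-shape vertex glyphs —
plus a seeded synthetic leaf-series generator so the whole pipeline is
testable without downloading any data.

## A worked example

Two synthetic "genera" share the heteroblastic/ontogenetic program; the
second carries one divergent species active for relative node 0.3–0.7:

```r
library(leafmapper)
res <- run_leaf_analysis(demo_two_genus_config(seed = 1))
res
#> Leaf-shape analysis (seed 1, config 3d4606f3)
#>   genusA: 600 leaves; heteroblasty Mapper V=12 E=11 b1=0 spine monotonicity=1.00
#>   genusB: 600 leaves; heteroblasty Mapper V=14 E=14 b1=1 spine monotonicity=1.00
#>   joint LDA accuracy: 0.957
```

genusA's heteroblasty-lens Mapper is a pure spine — 12 vertices in a path
(`b1 = 0`), mean lens ascending monotonically: one conserved program.
genusB gains two extra vertices and a cycle (`b1 = 1`): the divergent
species leaves the spine mid-series and rejoins it near both ends. The
joint four-group LDA separates the genera on LD1 and shoot base vs growing
tip on LD2, with 0.957 training accuracy.

```r
summary(res$mappers$genusB$heteroblasty)
#> Mapper graph (lens 'heteroblasty'): 14 vertices, 14 edges
#>   components: 1  cycle rank b1: 1
#>   path-likeness: 0.86  spine monotonicity: 1.00

export_bundle(res, "results")   # GraphML/JSON/CSV tables, plots, manifest
```

Single stages are plain functions: `read_landmark_table()`,
`assign_relative_node()`, `gpa()`, `shape_pca()`, `shape_lda()`,
`leaf_mapper()`, `graph_diagnostics()`, `extract_primary_structure()`,
`plot_subway()`. A thin CLI for the end-to-end paths lives at
`inst/cli/leafmapper.R` (`synth` and `run` subcommands). The methods
vignette (`vignettes/leafmapper-methods.Rmd`) documents the model, the
parameter defaults and every numerical choice.

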