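---
title: "Mapping leaf-shape trajectories: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping leaf-shape trajectories: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafmapper)
```

## The problem

Leaves on a vine change shape in two confounded ways. *Heteroblasty* is the
node-to-node change in the developmental program along the shoot: the leaf
initiated at node 20 is built differently from the leaf at node 2.
*Ontogeny* is the developmental trajectory of one leaf, from initiation to
maturity; near the growing tip the youngest leaves are still expanding, so
tip-to-base differences mix both effects. Landmark-based morphometrics
represents each leaf as an ordered set of homologous 2-D points (15 for
grapevine, 21 for maracuyá in the datasets this package targets), flattened
to a vector `(x1, y1, ..., xn, yn)` — 30 numbers for a grapevine leaf.

Ordination (PCA, LDA) summarises such point clouds by projection, which can
hide trajectory structure: two species with the same *program* but
different average shapes look disjoint; species with wildly different
shapes but a conserved program look unrelated. The Mapper algorithm from
topological data analysis summarises the *connectivity* of the cloud
instead, and that is the summary this package implements.

## The Mapper construction

Given leaves `X` and a lens `f : X -> R`:

1. **Lens.** Either the first principal component score of the flattened
   landmark vectors (`lens_pc1()`), or the heteroblasty value
   (`lens_heteroblasty()`): the leaf's relative node position in `[0, 1]`,
   0 at the growing tip and 1 at the shoot base. Relative position is the
   *rank* of the node within its vine, scaled to `[0, 1]`, so vines with
   missing nodes still span the full range; vines with one leaf are
   excluded (the denominator N−1 is undefined).
2. **Cover.** `build_cover(lens, n_intervals, overlap)` lays
   `n_intervals` equal-length intervals over the lens range, consecutive
   intervals overlapping by the fraction `overlap` of their length:
   interval length is `(M−m) / (n − (n−1)g)`. The intervals are *closed*:
   with finite data an open cover would drop the extreme leaves. A value
   falling in an overlap belongs to both intervals — this is what creates
   edges.
3. **Preimage clustering.** Within each interval's preimage,
   `cluster_preimage()` runs DBSCAN on the precomputed correlation
   distances: `d(u, v) = 1 − r(u, v)`, Pearson's r between the two
   flattened vectors, a semi-metric in `[0, 2]` that is invariant to
   positive affine maps of a vector — overall size changes are invisible,
   shape changes are not. DBSCAN is used because it does not fix the
   number of clusters and tolerates outliers; points that support no
   cluster are recorded as noise, per interval.
4. **Nerve.** One vertex per cluster, an edge wherever two clusters share
   a leaf. `nerve_oracle()` is a deliberately naive re-implementation of
   this last step (exhaustive pairwise intersection) used only as a test
   reference.

Vertices carry their members, mean lens value, group-label composition and
mean shape. `graph_diagnostics()` quantifies the qualitative readings:

* components `C` and cycle rank `b1 = |E| − |V| + C` — a branch that
  rejoins the spine adds one to `b1`;
* path-likeness — the fraction of vertices with degree ≤ 2;
* the **spine** — realized as the longest shortest path (graph diameter)
  of the largest component, oriented so mean lens ascends — and its
  monotonicity, the Spearman correlation of position along the spine with
  vertex mean lens. The source figures never define "central spine"
  algorithmically; the diameter-path realization is this package's choice,
  and `extract_primary_structure()` (size-threshold, then largest
  component) is likewise one defensible reading of "primary structure".

### Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `n_intervals` | 12 | — | resolution of the cover; more intervals, more vertices |
| `overlap` | 0.35 | fraction of interval length | edge density; must stay < 0.5 for points to lie in ≤ 2 intervals |
| `eps` | 0.05 | correlation-distance | DBSCAN neighborhood radius |
| `min_samples` | 5 | leaves | DBSCAN core-point threshold |

Mapper covers are tuned by hand to taste in practice; every parameter of a
run is stored in the graph's `params` so no output depends on hidden
defaults. All four defaults here were chosen once for the synthetic study
conditions below and are recorded with every graph.

## Procrustes and ordination stages

For the cross-genus morphospace the two landmark schemes are reduced to
their six shared points (petiolar-junction base, proximal lobe tip and
sinus, distal lobe tip and sinus, leaf tip; `subset_shared_landmarks()`),
half-digitized grapevine leaves are completed by mirroring the non-axis
landmarks across the petiolar-junction-to-tip midline
(`reflect_to_complete()`), and everything is superimposed by generalized
Procrustes analysis (`gpa()`): center, scale to unit centroid size, rotate
to the running mean, re-estimate, to convergence (`tol = 1e-7`, at most
100 iterations; the source states neither, these are ordinary choices).
Rotations are always proper — leaf handedness is biologically meaningful,
so mirror images are never introduced implicitly; an `allow_reflection`
flag exists for the variant behavior. Because a Procrustes fit is defined
only up to one global rotation, the converged configuration is reported in
a canonical orientation (principal axes of the mean shape, deterministic
sign), which makes `gpa()` exactly invariant under a common similarity
transform of its input — a property the test suite checks.

PCA is `stats::prcomp` behind a deterministic sign convention (each
component's largest-magnitude loading is positive) so that lens values and
plots are reproducible; the morphospace is visualized by the inverse
transform on a score grid (`morphospace_grid()`). LDA is Fisher's
between/within generalized eigenproblem, written out because the contract
needs two things off-the-shelf fits do not expose: the same deterministic
sign convention, and ridge regularization `λ = 1e-6 · tr(Sw)/p` when the
within-class scatter is singular — which it *always* is after GPA
(superimposition removes four degrees of freedom). `MASS::lda` is used in
the tests as an independent cross-check of the discriminant scores, never
as the implementation.

The four LDA groups are genus × position, with position from the
relative-node threshold split (`split_by_position(0.5)`, boundary leaves
going to the tip part, matching the ≤ of the series rule);
ontogenetic/heteroblastic series labels from the per-vine-mean rule
(`split_by_vine_mean()`) are emitted alongside in the score table.

## What the synthetic generator emulates

`synth_leaf_series()` generates species × vines × ordered node series on a
fixed three-lobed template curve, with four displacement components:

* a **shared heteroblastic trajectory** — lobe deepening and aspect change
  growing linearly with relative node position `r` (amplitude 1 by
  default);
* **ontogenetic allometry** — contraction and elongation growing with
  `1 − r`, strongest at the growing tip (amplitude 1; the tip of a real
  vine shows dramatic allometric change, and a strong common position
  effect is what lets the position contrast surface on the second
  discriminant axis rather than tying with the genus × position
  interaction);
* fixed random **species offset fields** (sd 0.02) and optionally one
  **genus offset field** (sd 0.12 in the two-genus demo) — species- and
  genus-level shape differences that do not alter the program;
* for divergent species, a **mid-series divergence**: a fixed displacement
  field scaled by a smooth bump over `r ∈ [0.3, 0.7]` that vanishes at
  both band edges — the branch-and-rejoin ("reverse hourglass") signal —
  plus i.i.d. Gaussian landmark noise (sd 0.01).

Study conditions are 4 species × 5 vines × 30 nodes per vine (600 leaves
per genus). The real datasets average roughly forty leaves per vine across
hundreds of vines; 30 nodes is the desk-scale analogue, and it matters for
a second reason: the heteroblasty lens is discrete (one value per node
rank), so the node spacing must be finer than the cover overlap width
(≈ 0.043 at the default cover) or consecutive intervals share no leaves
and the spine disconnects. The divergence amplitude default (0.15, 15× the
noise sd) was calibrated by simulation before the tests were frozen:
much larger amplitudes break the DBSCAN chain *along* the branch (the
displacement between adjacent nodes exceeds `eps`), so the branch
fragments instead of rejoining. The draw order (genus field, then species
fields, then per-leaf noise) is fixed so that adding vines never perturbs
the species effects.

What the generator does **not** emulate: real landmark digitization error
structure, within-vine serial correlation of environmental effects,
phylogenetic covariance among species offsets, or botanically realistic
outlines (a parametric template with controllable effect sizes is the
point, not realism). Passing recovery tests therefore show that the
pipeline detects the *kind* of structure the analysis claims to detect at
realistic effect-to-noise ratios — not that any particular real dataset
has that structure.

## Recovery experiments

Two seeded experiments anchor the test suite (20 seeds each):

* **Core program:** all species share the trajectory → the
  heteroblasty-lens Mapper graph must be acyclic (`b1 = 0`), path-like
  (≥ 80 % of vertices with degree ≤ 2), with spine monotonicity ≥ 0.95.
* **Divergent morphotype:** one species of a genus-offset dataset diverges
  in `r ∈ [0.3, 0.7]` → the graph must gain a cycle (`b1 ≥ 1`) whose
  off-spine vertices are majority-divergent by composition. The genus
  offset is part of this condition because the divergent morphotypes of
  the motivating data live in a genus of their own.

The partial-dataset experiment splits the divergent dataset at
`relative_node = 0.5` and rebuilds each half's Mapper over its own lens
range (each partial dataset is treated as a fresh analysis); each half
must contain only its own leaves and show the branch signature, since the
divergence band straddles the split.

## Numerical choices and degenerate inputs

* Cover: the last interval end is pinned to the lens maximum to guard
  round-off; a zero-width lens range is an error unless `n_intervals = 1`.
* DBSCAN: a point counts itself among its neighbors; border points join
  the first cluster that reaches them in input order, making results
  deterministic for a fixed dataset order (datasets are always sorted by
  vine, node, leaf id).
* Cluster ids within an interval are ordered by each cluster's
  first-appearing member, so vertex ids (`i<interval>_c<cluster>`) are
  reproducible.
* Degenerate shapes (all landmarks coincident) and constant flattened
  vectors (undefined Pearson correlation) raise errors naming the leaf.
* Ties in `extract_primary_structure()`'s largest-component rule break
  toward the component containing the lexicographically smallest vertex
  id.

## A worked run

```{r demo, eval = FALSE}
cfg <- demo_two_genus_config(seed = 1)
res <- run_leaf_analysis(cfg)
res
summary(res$mappers$genusB$heteroblasty)
manifest <- export_bundle(res, "results")
```

The bundle contains GraphML/JSON per graph, membership and score tables,
model JSONs, diagnostics, static plots and an MD5-checksummed manifest;
identical configurations produce byte-identical text outputs.

## Known limitations

* One-dimensional lenses only; no persistent homology; no interactive
  graph viewer.
* The spine and primary-structure definitions are package choices; other
  defensible realizations (e.g. weighted longest path, centrality-based
  trunks) would differ on graphs with long competing branches.
* Exact reproduction of the published Mapper figures is out of reach in
  principle: their interval counts, overlaps and DBSCAN settings were
  hand-tuned and not reported. The package therefore validates properties
  (spine, monotonicity, branch-and-rejoin) rather than figure shapes.
* Mapper distances default to raw (unaligned) flattened coordinates,
  matching the described workflow; `align = TRUE` switches to
  GPA-superimposed input, and whether the original PC1 lens was computed
  on aligned coordinates is unknown.
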