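test_that("correlation distance follows the Pearson formula", {
  expect_equal(correlation_distance(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0)
  expect_equal(correlation_distance(c(1, 2, 3, 4), c(4, 3, 2, 1)), 2)
  # independent textbook-formula oracle
  u <- c(1, 2, 3); v <- c(1, 2, 4)
  r <- sum((u - mean(u)) * (v - mean(v))) /
    sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  expect_equal(correlation_distance(u, v), 1 - r, tolerance = 1e-12)
  expect_error(correlation_distance(c(1, 1, 1), c(1, 2, 3)),
               "constant")
  expect_error(correlation_distance(c(1, 2), c(1, 2)), "length")
})

test_that("correlation distance is affine-invariant and bounded", {
  set.seed(12)
  for (rep in 1:20) {
    u <- rnorm(10L)
    a <- runif(1L, 0.1, 10); b <- rnorm(1L)
    expect_lt(correlation_distance(u, a * u + b), 1e-10)
    v <- rnorm(10L)
    d <- correlation_distance(u, v)
    expect_gte(d, 0); expect_lte(d, 2)
    expect_equal(d, correlation_distance(v, u), tolerance = 1e-12)
  }
})

test_that("pairwise distances match a naive double loop", {
  V <- random_vectors(5L, 8L, seed = 99L)
  dm <- pairwise_distances(V)
  for (i in 1:5) for (j in 1:5) {
    want <- if (i == j) 0 else correlation_distance(V[i, ], V[j, ])
    expect_equal(dm$d[i, j], want, tolerance = 1e-12)
  }
  expect_identical(dm$d, t(dm$d))
  # identical vectors at distance zero
  dup <- rbind(V[1, ], V[1, ])
  expect_equal(max(abs(pairwise_distances(dup)$d)), 0, tolerance = 1e-12)
  # constant vector is flagged with the leaf name
  bad <- V; bad[3L, ] <- 1
  expect_error(pairwise_distances(bad), "L003")
})

test_that("lenses assign one value per leaf, independent of row order", {
  ds <- assign_relative_node(synth_leaf_series(synth_config(
    n_species = 2L, vines_per_species = 2L, nodes_per_vine = 5L, seed = 4L)))
  lh <- lens_heteroblasty(ds)
  expect_equal(unname(lh$values[ds$meta$leaf_id]), ds$meta$relative_node)
  expect_equal(unname(lh$values[ds$meta$leaf_id[ds$meta$node_index == 1L]]),
               rep(0, 4L))
  # permuting the dataset leaves the id -> value mapping unchanged
  perm <- ds[rev(seq_len(n_leaves(ds)))]
  lh2 <- lens_heteroblasty(perm)
  expect_equal(lh2$values[names(lh$values)], lh$values)

  # pc1 lens equals the eigendecomposition projection up to sign
  V <- flatten_leaves(ds)
  lp <- lens_pc1(ds)
  eig <- eigen(cov(V), symmetric = TRUE)
  oracle <- drop(sweep(V, 2L, colMeans(V)) %*% eig$vectors[, 1L])
  expect_equal(abs(unname(lp$values)), abs(unname(oracle)), tolerance = 1e-8)
  # the lens is centered: a mean-vector leaf would score 0
  expect_lt(abs(mean(lp$values)), 1e-8)
})

test_that("cover intervals follow the stated arithmetic", {
  cov1 <- build_cover(c(0.2, 0.9), n_intervals = 1L, overlap = 0.3)
  expect_equal(unname(cov1$intervals), cbind(0.2, 0.9))
  cov2 <- build_cover(c(0, 1), n_intervals = 2L, overlap = 0)
  expect_equal(unname(cov2$intervals), cbind(c(0, 0.5), c(0.5, 1)))
  # n = 3, g = 1/3 over [0, 1]: length 3/7, starts at 0, 2/7, 4/7
  cov3 <- build_cover(c(0, 1), n_intervals = 3L, overlap = 1 / 3)
  expect_equal(unname(cov3$intervals),
               cbind(c(0, 2, 4) / 7, c(3, 5, 7) / 7), tolerance = 1e-12)
  # overlap of consecutive intervals is exactly g * length
  ovl <- unname(cov3$intervals[1L, 2L] - cov3$intervals[2L, 1L])
  expect_equal(ovl, (1 / 3) * (3 / 7), tolerance = 1e-12)
  expect_error(build_cover(c(1, 1), n_intervals = 3L), "degenerate")
  expect_s3_class(build_cover(c(1, 1), n_intervals = 1L), "mapper_cover")
})

test_that("cover membership: full coverage, <= 2 intervals when g < 0.5", {
  set.seed(31)
  for (rep in 1:20) {
    vals <- runif(40L)
    n_int <- sample(2:10, 1L)
    g <- runif(1L, 0, 0.49)
    cov <- build_cover(vals, n_int, g)
    pre <- cover_preimages(cov, vals)
    counts <- tabulate(unlist(pre), nbins = length(vals))
    expect_true(all(counts >= 1L))
    expect_true(all(counts <= 2L))
    # intervals have equal length and span the range
    lens <- cov$intervals[, 2L] - cov$intervals[, 1L]
    expect_lt(max(lens) - min(lens), 1e-9)
    expect_equal(unname(cov$intervals[1L, 1L]), min(vals))
    expect_equal(unname(cov$intervals[n_int, 2L]), max(vals))
  }
})

test_that("preimage clustering has DBSCAN semantics", {
  # two tight groups far apart: oracle = transitive closure within eps
  ids <- sprintf("p%d", 1:6)
  pos <- c(0, 0.01, 0.02, 1, 1.01, 1.02)
  d <- abs(outer(pos, pos, `-`))
  dimnames(d) <- list(ids, ids)
  dmat <- structure(list(ids = ids, d = d), class = "leaf_dist")
  got <- cluster_preimage(ids, dmat, eps = 0.05, min_samples = 1L)
  oracle <- closure_clusters(ids, dmat, eps = 0.05)
  expect_equal(lapply(got$clusters, sort), oracle)
  expect_length(got$clusters, 2L)
  expect_length(got$noise, 0L)

  # min_samples = 1 with eps >= max distance: one all-point cluster
  all_in <- cluster_preimage(ids, dmat, eps = 2, min_samples = 1L)
  expect_length(all_in$clusters, 1L)
  expect_setequal(all_in$clusters[[1L]], ids)

  # an isolated point with min_samples = 2 is noise
  iso <- cluster_preimage(c("p1", "p4"), dmat, eps = 0.05, min_samples = 2L)
  expect_length(iso$clusters, 0L)
  expect_setequal(iso$noise, c("p1", "p4"))

  # empty member list
  empty <- cluster_preimage(character(), dmat, eps = 0.1, min_samples = 1L)
  expect_length(empty$clusters, 0L)
  expect_length(empty$noise, 0L)
})

test_that("preimage clustering matches the closure oracle on random inputs", {
  set.seed(88)
  for (rep in 1:15) {
    n <- sample(5:25, 1L)
    V <- matrix(rnorm(n * 6L), n, 6L)
    rownames(V) <- sprintf("r%02d", seq_len(n))
    dmat <- pairwise_distances(V)
    eps <- runif(1L, 0.2, 1.5)
    got <- cluster_preimage(dmat$ids, dmat, eps, min_samples = 1L)
    oracle <- closure_clusters(dmat$ids, dmat, eps)
    expect_equal(lapply(got$clusters, sort)[order(vapply(got$clusters, min, ""))],
                 oracle[order(vapply(oracle, min, ""))])
  }
})

test_that("a hand-built line fixture yields the expected nerve", {
  # six leaves along a line; lens = position; 2 overlapping intervals;
  # all pairwise distances small, so each preimage is one cluster
  set.seed(5)
  base <- sin(1:9)
  V <- t(vapply(seq(0, 1, length.out = 6L), function(s)
    base + s * cos(1:9) * 0.5, numeric(9L)))
  rownames(V) <- sprintf("leaf%d", 1:6)
  meta <- data.frame(leaf_id = rownames(V), group_label = "g",
                     vine_id = "v", node_index = 1:6)
  ds <- leaf_dataset(landmark_scheme("line", sprintf("l%d", 1:4)),
                     meta, V[, 1:8])
  ds <- assign_relative_node(ds)
  m <- leaf_mapper(ds, "heteroblasty", n_intervals = 2L, overlap = 0.34,
                   eps = 1.9, min_samples = 1L)
  expect_length(m$vertices, 2L)
  expect_equal(nrow(m$edges), 1L)
  # interval length 1/1.66: lens values 0.4 and 0.6 fall in both intervals
  expect_equal(m$edges$weight, 2L)
  # vertex ids follow the interval/cluster convention
  expect_setequal(vapply(m$vertices, `[[`, character(1L), "vertex_id"),
                  c("i1_c1", "i2_c1"))

  # far-separated lens clusters with no overlap member: no edges
  ds2 <- ds
  ds2$meta$relative_node <- c(0, 0.01, 0.02, 0.98, 0.99, 1)
  m2 <- leaf_mapper(ds2, lens = lens_heteroblasty(ds2), n_intervals = 2L,
                    overlap = 0.1, eps = 1.9, min_samples = 1L)
  expect_equal(nrow(m2$edges), 0L)
  expect_equal(graph_diagnostics(m2)$n_components, 2L)
})

test_that("build_mapper agrees with the brute-force nerve oracle", {
  set.seed(2024)
  for (rep in 1:25) {
    n <- sample(8:30, 1L)
    p <- sample(c(6L, 8L), 1L)
    V <- matrix(rnorm(n * p), n, p)
    rownames(V) <- sprintf("x%02d", seq_len(n))
    meta <- data.frame(leaf_id = rownames(V),
                       group_label = sample(c("a", "b"), n, TRUE),
                       vine_id = "v", node_index = seq_len(n))
    ds <- leaf_dataset(landmark_scheme(sprintf("s%d", p),
                                       sprintf("l%d", seq_len(p / 2L))),
                       meta, V)
    ds <- assign_relative_node(ds)
    m <- suppressWarnings(leaf_mapper(ds, "heteroblasty",
                     n_intervals = sample(2:6, 1L),
                     overlap = runif(1L, 0.1, 0.45),
                     eps = runif(1L, 0.5, 1.5),
                     min_samples = sample(1:3, 1L)))
    clusters <- lapply(m$vertices, function(v)
      list(vertex_id = v$vertex_id, interval_index = v$interval_index,
           members = v$members))
    oracle <- nerve_oracle(clusters)
    # identical memberships (by construction) and identical edge sets
    key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
    expect_setequal(key(m$edges), key(oracle$edges))
    expect_equal(m$edges$weight[order(key(m$edges))],
                 oracle$edges$weight[order(key(oracle$edges))])
  }
})

test_that("membership conservation: vertices plus noise cover every point", {
  ds <- assign_relative_node(synth_leaf_series(synth_config(
    n_species = 2L, vines_per_species = 2L, nodes_per_vine = 10L,
    noise_sd = 0.05, seed = 3L)))
  m <- leaf_mapper(ds, "heteroblasty", n_intervals = 5L, overlap = 0.3,
                   eps = 0.05, min_samples = 3L)
  cov <- build_cover(lens_heteroblasty(ds), 5L, 0.3)
  pre <- cover_preimages(cov, ds$meta$relative_node)
  expected_occurrences <- sum(lengths(pre))
  placed <- sum(vapply(m$vertices, function(v) length(v$members), integer(1L))) +
    length(unlist(m$noise))
  expect_equal(placed, expected_occurrences)
  expect_setequal(
    union(unlist(lapply(m$vertices, `[[`, "members")), unlist(m$noise)),
    ds$meta$leaf_id)
  # edges connect same or adjacent intervals only (overlap < 0.5)
  iv <- setNames(vapply(m$vertices, `[[`, integer(1L), "interval_index"),
                 vapply(m$vertices, `[[`, character(1L), "vertex_id"))
  if (nrow(m$edges))
    expect_true(all(abs(iv[m$edges$from] - iv[m$edges$to]) <= 1L))
})

test_that("vertex annotations are consistent", {
  ds <- assign_relative_node(synth_leaf_series(synth_config(
    n_species = 2L, vines_per_species = 2L, nodes_per_vine = 8L, seed = 6L)))
  m <- leaf_mapper(ds, "heteroblasty", n_intervals = 4L, overlap = 0.3,
                   eps = 0.1, min_samples = 2L)
  rn <- setNames(ds$meta$relative_node, ds$meta$leaf_id)
  for (v in m$vertices) {
    expect_equal(sum(v$composition), 1, tolerance = 1e-9)
    expect_equal(v$mean_lens, mean(rn[v$members]), tolerance = 1e-12)
    expect_equal(v$size, length(v$members))
    want_shape <- colMeans(flatten_leaves(ds)[v$members, , drop = FALSE])
    expect_equal(as.vector(t(v$mean_shape)), unname(want_shape),
                 tolerance = 1e-12)
  }
})

test_that("graph diagnostics count components, cycles and path-likeness", {
  path5 <- nerve_oracle(lapply(1:5, function(i)
    list(members = c(sprintf("m%d", i), sprintf("m%d", i + 1L)),
         interval_index = i)))
  d <- graph_diagnostics(path5)
  expect_equal(d$n_vertices, 5L); expect_equal(d$n_edges, 4L)
  expect_equal(d$n_components, 1L); expect_equal(d$cycle_rank, 0L)
  expect_equal(d$path_likeness, 1.0)

  cyc5 <- nerve_oracle(lapply(1:5, function(i)
    list(members = c(sprintf("m%d", i), sprintf("m%d", i %% 5L + 1L)),
         interval_index = i)))
  expect_equal(graph_diagnostics(cyc5)$cycle_rank, 1L)

  # disjoint path (3 vertices) + cycle (4 vertices): additivity
  mixed <- nerve_oracle(c(
    lapply(1:3, function(i)
      list(members = c(sprintf("p%d", i), sprintf("p%d", i + 1L)),
           interval_index = i)),
    lapply(1:4, function(i)
      list(members = c(sprintf("q%d", i), sprintf("q%d", i %% 4L + 1L)),
           interval_index = i))))
  dm <- graph_diagnostics(mixed)
  expect_equal(dm$n_components, 2L)
  expect_equal(dm$cycle_rank, 6L - 7L + 2L)

  # empty graph: zero record with flag
  empty <- nerve_oracle(list())
  de <- graph_diagnostics(empty)
  expect_true(de$empty)
  expect_equal(de$n_vertices, 0L)
})

test_that("spine mean lens is monotone on single-trajectory data", {
  ds <- assign_relative_node(synth_leaf_series(synth_config(seed = 17L)))
  m <- leaf_mapper(ds, "heteroblasty")
  d <- graph_diagnostics(m)
  expect_gte(d$spine_monotonicity, 0.95)
  ml <- setNames(vapply(m$vertices, `[[`, numeric(1L), "mean_lens"),
                 vapply(m$vertices, `[[`, character(1L), "vertex_id"))
  expect_true(all(diff(ml[d$spine]) > 0))
})

test_that("mapper exports write graphml, json and membership tables", {
  ds <- assign_relative_node(synth_leaf_series(synth_config(
    n_species = 1L, vines_per_species = 2L, nodes_per_vine = 10L, seed = 23L)))
  m <- leaf_mapper(ds, "heteroblasty", n_intervals = 4L, overlap = 0.3,
                   eps = 0.1, min_samples = 2L)
  g <- withr::local_tempfile(fileext = ".graphml")
  j <- withr::local_tempfile(fileext = ".json")
  cs <- withr::local_tempfile(fileext = ".csv")
  write_mapper_graphml(m, g)
  back <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::vcount(back), length(m$vertices))
  expect_equal(igraph::ecount(back), nrow(m$edges))
  write_mapper_json(m, j)
  doc <- jsonlite::read_json(j)
  expect_length(doc$vertices, length(m$vertices))
  expect_equal(doc$params$eps, 0.1)
  write_mapper_membership(m, cs)
  tab <- read.csv(cs)
  expect_equal(nrow(tab),
               sum(vapply(m$vertices, function(v) length(v$members),
                          integer(1L))))
})
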