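test_that("landmark tables read, validate and round-trip", {
  ds <- tiny_dataset(data.frame(vine = rep(c("v1", "v2"), each = 3L),
                                node = rep(1:3, 2L)),
                     n_landmarks = 15L,
                     scheme = builtin_scheme("grapevine"))
  expect_equal(n_leaves(ds), 6L)
  expect_equal(ncol(flatten_leaves(ds)), 30L)

  path <- withr::local_tempfile(fileext = ".csv")
  write_landmark_table(ds, path)
  back <- read_landmark_table(path, builtin_scheme("grapevine"))
  expect_identical(back$meta, ds$meta)
  expect_identical(unname(back$coords), unname(ds$coords))
  # second round trip is bitwise stable
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_landmark_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("table ingestion rejects bad schemas and bad rows", {
  df <- data.frame(leaf_id = c("a", "b"), group_label = "g",
                   vine_id = "v1", node_index = 1:2,
                   x1 = c(0, 1), y1 = c(0, 1), x2 = c(1, 2), y2 = c(0, 1),
                   x3 = c(0.5, 1), y3 = c(1, 2))
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, p, row.names = FALSE)

  scheme3 <- landmark_scheme("tri", c("a", "b", "c"))
  expect_s3_class(read_landmark_table(p, scheme3), "leaf_dataset")
  # wrong coordinate-column count for the scheme
  expect_error(read_landmark_table(p, builtin_scheme("grapevine")),
               "schema error")
  # non-numeric coordinate names the row
  df_bad <- df; df_bad$x2[2L] <- "oops"
  write.csv(df_bad, p, row.names = FALSE)
  expect_error(read_landmark_table(p, scheme3), "row")
  # duplicate leaf ids
  df_dup <- df; df_dup$leaf_id <- c("a", "a")
  write.csv(df_dup, p, row.names = FALSE)
  expect_error(read_landmark_table(p, scheme3), "duplicate")
  # empty table with a valid header is fine
  write.csv(df[0L, ], p, row.names = FALSE)
  expect_equal(n_leaves(read_landmark_table(p, scheme3)), 0L)
  # rows with missing coordinates are dropped with a warning
  df_na <- df; df_na$y3[1L] <- NA
  write.csv(df_na, p, row.names = FALSE)
  expect_warning(got <- read_landmark_table(p, scheme3), "missing")
  expect_equal(n_leaves(got), 1L)
})

test_that("JSON serialization round-trips a dataset", {
  ds <- assign_relative_node(
    tiny_dataset(data.frame(vine = rep("v1", 3L), node = 1:3)))
  p <- withr::local_tempfile(fileext = ".json")
  dataset_to_json(ds, p)
  back <- dataset_from_json(p)
  expect_identical(back$meta, ds$meta)
  expect_equal(unname(back$coords), unname(ds$coords))
})

test_that("relative node runs 0 at the tip to 1 at the base, by rank", {
  ds <- tiny_dataset(data.frame(vine = "v1", node = 1:5))
  out <- assign_relative_node(ds)
  expect_equal(out$meta$relative_node, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(out$meta$relative_node[out$meta$node_index == 1L], 0)
  expect_equal(out$meta$relative_node[out$meta$node_index == 5L], 1)

  # two-node vine hits both endpoints
  out2 <- assign_relative_node(tiny_dataset(data.frame(vine = "v", node = 1:2)))
  expect_equal(sort(out2$meta$relative_node), c(0, 1))

  # gaps in the node series: ranks, not raw indices
  out3 <- assign_relative_node(
    tiny_dataset(data.frame(vine = "v", node = c(3L, 5L, 9L))))
  expect_equal(out3$meta$relative_node, c(0, 0.5, 1))

  # input unchanged
  expect_true(all(is.na(ds$meta$relative_node)))
})

test_that("relative node guards degenerate vines and duplicates", {
  scheme <- landmark_scheme("t4", sprintf("p%d", 1:4))
  dup <- leaf_dataset(scheme,
                      data.frame(leaf_id = c("a", "b", "c"),
                                 group_label = "g", vine_id = "v",
                                 node_index = c(1L, 1L, 2L)),
                      matrix(rep(c(1, 0, 0, 1, -1, 0, 0, -1), 3L), 3L,
                             byrow = TRUE))
  expect_error(assign_relative_node(dup), "duplicate")
  singleton <- tiny_dataset(data.frame(vine = c("v1", "v1", "v2"),
                                       node = c(1L, 2L, 1L)))
  expect_warning(out <- assign_relative_node(singleton), "single-leaf")
  expect_equal(unique(out$meta$vine_id), "v1")
  all_single <- tiny_dataset(data.frame(vine = c("v1", "v2"), node = c(1L, 1L)))
  expect_error(suppressWarnings(assign_relative_node(all_single)), "relative node")
})

test_that("relative node values per vine are increasing, spanning [0, 1]", {
  ds <- assign_relative_node(synth_leaf_series(synth_config(
    n_species = 2L, vines_per_species = 2L, nodes_per_vine = 7L, seed = 11L)))
  for (v in unique(ds$meta$vine_id)) {
    idx <- ds$meta$vine_id == v
    rn <- ds$meta$relative_node[idx][order(ds$meta$node_index[idx])]
    expect_true(all(diff(rn) > 0))
    expect_equal(range(rn), c(0, 1))
  }
})

test_that("shared-landmark subsetting reduces the scheme faithfully", {
  ds <- tiny_dataset(data.frame(vine = "v", node = 1:2), n_landmarks = 21L,
                     scheme = builtin_scheme("maracuya"))
  sub <- subset_shared_landmarks(ds, c(1L, 4L, 7L, 12L, 17L, 21L))
  expect_equal(sub$scheme$n_landmarks, 6L)
  expect_equal(leaf_landmarks(sub, 1L)[3L, ],
               leaf_landmarks(ds, 1L)[7L, ])
  # identity selection leaves coordinates unchanged
  idm <- subset_shared_landmarks(ds, seq_len(21L))
  expect_equal(unname(idm$coords), unname(ds$coords))
  expect_error(subset_shared_landmarks(ds, integer()), "empty")
  expect_error(subset_shared_landmarks(ds, c(1L, 22L)), "index error")
})

test_that("reflection completion mirrors landmarks across the midline", {
  # hand-computed oracle: reflection across the line through a and b is
  # p' = a + H (p - a), H the Householder-style matrix 2uu' - I
  a <- c(0, 0); b <- c(1, 2)
  u <- (b - a) / sqrt(sum((b - a)^2))
  H <- 2 * tcrossprod(u) - diag(2)
  pts <- rbind(a, c(0.7, 0.1), c(0.2, 0.9), c(-0.4, 0.5), b)
  mirror <- t(apply(pts[2:4, ], 1L, function(p) a + H %*% (p - a)))

  scheme <- landmark_scheme("half", sprintf("p%d", 1:5),
                            axis_indices = c(1L, 5L))
  ds <- leaf_dataset(scheme,
                     data.frame(leaf_id = "L1", group_label = "g",
                                vine_id = "v", node_index = 1L),
                     matrix(as.vector(t(pts)), 1L))
  full <- reflect_to_complete(ds)
  expect_equal(full$scheme$n_landmarks, 5L + 3L)
  got <- leaf_landmarks(full, 1L)
  expect_equal(unname(got[6:8, ]), unname(mirror), tolerance = 1e-12)
  # equidistance from both axis points
  for (k in 2:4)
    for (ax in list(a, b))
      expect_equal(sum((got[k, ] - ax)^2), sum((got[k + 4L, ] - ax)^2),
                   tolerance = 1e-12)
})

test_that("reflection is an involution and fixes axis-line points", {
  # a point on the axis mirrors onto itself
  a <- c(0, -1); b <- c(0, 3)
  on_axis <- matrix(c(0, 1), 1L)
  scheme <- landmark_scheme("half3", c("a", "m", "b"), axis_indices = c(1L, 3L))
  ds <- leaf_dataset(scheme,
                     data.frame(leaf_id = "L", group_label = "g",
                                vine_id = "v", node_index = 1L),
                     matrix(c(a, on_axis, b), 1L))
  got <- leaf_landmarks(reflect_to_complete(ds), 1L)
  expect_equal(unname(got[4L, ]), c(0, 1), tolerance = 1e-12)

  # axis = y-axis: (1, 2) reflects to (-1, 2)
  ds2 <- leaf_dataset(scheme,
                      data.frame(leaf_id = "L", group_label = "g",
                                 vine_id = "v", node_index = 1L),
                      matrix(c(0, -1, 1, 2, 0, 3), 1L))
  got2 <- leaf_landmarks(reflect_to_complete(ds2), 1L)
  expect_equal(unname(got2[4L, ]), c(-1, 2), tolerance = 1e-12)

  # involution: reflecting the mirrored point recovers the original
  set.seed(42)
  for (rep in 1:5) {
    p <- matrix(rnorm(2L), 1L)
    a <- rnorm(2L); b <- rnorm(2L)
    m <- leafmapper:::reflect_points(p, a, b)
    expect_equal(leafmapper:::reflect_points(m, a, b), p, tolerance = 1e-9)
  }

  # coincident axis landmarks are a geometry error
  expect_error(leafmapper:::reflect_points(matrix(1:2, 1L), c(1, 1), c(1, 1)),
               "geometry error")
})

test_that("position split partitions at the threshold, boundary to the tip", {
  ds <- tiny_dataset(data.frame(vine = "v", node = 1:5))
  ds <- assign_relative_node(ds)   # 0, .25, .5, .75, 1
  parts <- split_by_position(ds, 0.5)
  expect_equal(sort(parts$tip$meta$relative_node), c(0, 0.25, 0.5))
  expect_equal(sort(parts$base$meta$relative_node), c(0.75, 1))
  expect_setequal(c(parts$tip$meta$leaf_id, parts$base$meta$leaf_id),
                  ds$meta$leaf_id)
  # all leaves at 1.0 -> base gets everything
  ds2 <- ds; ds2$meta$relative_node <- rep(1, 5L)
  parts2 <- split_by_position(ds2, 0.5)
  expect_equal(n_leaves(parts2$tip), 0L)
  expect_equal(n_leaves(parts2$base), 5L)
  # unassigned relative node is a state error
  expect_error(split_by_position(tiny_dataset(data.frame(vine = "v", node = 1:2))),
               "state error")
  expect_error(split_by_position(ds, 1.2), "threshold")
})

test_that("per-vine-mean split assigns series within each vine separately", {
  ds <- assign_relative_node(tiny_dataset(data.frame(vine = "v", node = 1:3)))
  parts <- split_by_vine_mean(ds)   # values 0, .5, 1; mean .5
  expect_equal(sort(parts$ontogenetic$meta$relative_node), c(0, 0.5))
  expect_equal(parts$heteroblastic$meta$relative_node, 1)

  # single repeated value: everything ontogenetic
  ds2 <- ds; ds2$meta$relative_node <- rep(0.4, 3L)
  parts2 <- split_by_vine_mean(ds2)
  expect_equal(n_leaves(parts2$ontogenetic), 3L)

  # two vines with different means: brute-force per-vine membership
  ds3 <- assign_relative_node(tiny_dataset(
    data.frame(vine = rep(c("v1", "v2"), c(3L, 5L)),
               node = c(1:3, 1:5))))
  parts3 <- split_by_vine_mean(ds3)
  expected_onto <- unlist(lapply(split(seq_len(8L), ds3$meta$vine_id),
    function(idx) ds3$meta$leaf_id[idx][
      ds3$meta$relative_node[idx] <= mean(ds3$meta$relative_node[idx])]))
  expect_setequal(parts3$ontogenetic$meta$leaf_id, expected_onto)
  expect_setequal(c(parts3$ontogenetic$meta$leaf_id,
                    parts3$heteroblastic$meta$leaf_id), ds3$meta$leaf_id)
})
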