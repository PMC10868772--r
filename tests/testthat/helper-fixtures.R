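# fixture builders shared across the test files

# a tiny hand-specified dataset: `spec` is a data frame with columns
# vine, node, group (optional), and coordinates come from a deterministic
# function of (vine, node) unless supplied
tiny_dataset <- function(spec, n_landmarks = 4L, coords = NULL,
                         scheme = NULL) {
  if (is.null(scheme))
    scheme <- landmark_scheme(sprintf("test%d", n_landmarks),
                              sprintf("p%02d", seq_len(n_landmarks)))
  meta <- data.frame(
    leaf_id = sprintf("%s_n%02d", spec$vine, spec$node),
    group_label = if (!is.null(spec$group)) spec$group else "g",
    vine_id = spec$vine,
    node_index = spec$node,
    stringsAsFactors = FALSE)
  if (is.null(coords)) {
    coords <- t(vapply(seq_len(nrow(spec)), function(i) {
      base <- as.vector(t(cbind(cos(seq_len(n_landmarks)),
                                sin(seq_len(n_landmarks)))))
      base + 0.01 * spec$node[i] * seq_along(base)
    }, numeric(2L * n_landmarks)))
  }
  leaf_dataset(scheme, meta, coords)
}

# random non-degenerate shape-vector matrix with ids
random_vectors <- function(n, p, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p)
  rownames(m) <- sprintf("L%03d", seq_len(n))
  m
}

# apply a random similarity transform (rotation + translation + scale > 0)
# to every leaf of a dataset
apply_similarity <- function(ds, angle, shift, scale) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L, 2L)
  coords <- t(apply(flatten_leaves(ds), 1L, function(v) {
    p <- matrix(v, ncol = 2L, byrow = TRUE)
    p <- scale * p %*% t(R)
    p <- sweep(p, 2L, shift, `+`)
    as.vector(t(p))
  }))
  set_coords <- function(x, coords) {
    x$coords <- coords
    dimnames(x$coords) <- dimnames(flatten_leaves(ds))
    x
  }
  set_coords(ds, coords)
}

# independent clustering oracle: transitive closure of the "within eps"
# relation (DBSCAN with min_samples = 1)
closure_clusters <- function(ids, dmat, eps) {
  d <- dmat$d[ids, ids, drop = FALSE]
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, j] <= eps) parent[find(i)] <- find(j)
  roots <- vapply(seq_len(n), find, integer(1L))
  unname(lapply(split(ids, roots), sort))
}
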