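#' Correlation distance between shape vectors
#'
#' The semi-metric `1 - r`, with `r` the Pearson correlation of the two
#' flattened landmark vectors: leaves whose landmark coordinates are highly
#' correlated lie near distance zero; the range is [0, 2]. Constant vectors
#' have no defined correlation and raise an error.
#'
#' @param u,v Numeric vectors of equal length >= 3.
#' @return The correlation distance, a scalar in [0, 2].
#' @export
correlation_distance <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v) || length(u) < 3L)
    stop("vectors must have equal length >= 3", call. = FALSE)
  if (stats::sd(u) == 0 || stats::sd(v) == 0)
    stop("undefined correlation: constant vector", call. = FALSE)
  d <- 1 - stats::cor(u, v)
  min(max(d, 0), 2)
}

#' Pairwise correlation-distance matrix
#'
#' @param x A [leaf_dataset()] or a matrix of shape vectors (rows =
#'   leaves, rownames = ids).
#' @return An object of class `leaf_dist`: list with `ids` and the
#'   symmetric zero-diagonal matrix `d` of correlation distances.
#' @export
pairwise_distances <- function(x) {
  v <- if (inherits(x, "leaf_dataset")) flatten_leaves(x) else as.matrix(x)
  if (nrow(v) < 2L)
    stop("need at least 2 shape vectors", call. = FALSE)
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0))
    stop("undefined correlation: constant shape vector for leaf ",
         paste(rownames(v)[sds == 0], collapse = ", "), call. = FALSE)
  d <- 1 - stats::cor(t(v))
  d[d < 0] <- 0
  d[d > 2] <- 2
  diag(d) <- 0
  d <- (d + t(d)) / 2
  ids <- rownames(v) %||% as.character(seq_len(nrow(v)))
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d), class = "leaf_dist")
}

#' Lens functions
#'
#' A lens assigns one real value to every leaf; the overlapping-interval
#' cover is built over its range. `lens_heteroblasty()` uses the relative
#' node position (0 = growing tip, 1 = shoot base); `lens_pc1()` uses the
#' first principal component score of the flattened (unaligned) landmark
#' vectors.
#'
#' @param x A [leaf_dataset()] (for `lens_pc1`, alternatively a matrix of
#'   shape vectors).
#' @return An object of class `mapper_lens`: `ids`, `values`, `lens_name`.
#' @export
lens_heteroblasty <- function(x) {
  stopifnot(inherits(x, "leaf_dataset"))
  rn <- x$meta$relative_node
  if (anyNA(rn))
    stop("state error: relative_node unassigned; run assign_relative_node()",
         call. = FALSE)
  structure(list(ids = x$meta$leaf_id, values = stats::setNames(rn, x$meta$leaf_id),
                 lens_name = "heteroblasty"),
            class = "mapper_lens")
}

#' @rdname lens_heteroblasty
#' @export
lens_pc1 <- function(x) {
  v <- if (inherits(x, "leaf_dataset")) flatten_leaves(x) else as.matrix(x)
  model <- shape_pca(v, n_components = 1L)
  sc <- drop(pca_scores(model, v))
  ids <- rownames(v) %||% as.character(seq_len(nrow(v)))
  structure(list(ids = ids, values = stats::setNames(sc, ids),
                 lens_name = "pc1"),
            class = "mapper_lens")
}

#' @export
print.mapper_lens <- function(x, ...) {
  cat("Mapper lens '", x$lens_name, "': ", length(x$values),
      " values in [", format(min(x$values)), ", ", format(max(x$values)),
      "]\n", sep = "")
  invisible(x)
}

#' Build an overlapping-interval cover of a lens range
#'
#' Over the lens range [m, M], `n_intervals` equal-length closed intervals
#' are laid out so that consecutive intervals overlap by exactly the
#' `overlap` fraction of their length: length `l = (M - m) / (n - (n-1)*g)`
#' and interval k starts at `m + (k-1) * l * (1-g)`. Intervals are closed —
#' with finite data an open cover would drop the extreme leaves — and a
#' value falling in an overlap belongs to both intervals.
#'
#' @param lens A `mapper_lens`, or a numeric vector of lens values.
#' @param n_intervals Number of intervals (>= 1).
#' @param overlap Overlap fraction g in [0, 1).
#' @return An object of class `mapper_cover`: `n_intervals`, `overlap`,
#'   and `intervals` (n x 2 matrix of closed [start, end] pairs).
#' @export
build_cover <- function(lens, n_intervals = 12L, overlap = 0.35) {
  vals <- if (inherits(lens, "mapper_lens")) lens$values else as.numeric(lens)
  if (length(vals) < 1L) stop("lens has no values", call. = FALSE)
  n_intervals <- as.integer(n_intervals)
  if (n_intervals < 1L) stop("n_intervals must be >= 1", call. = FALSE)
  if (!(overlap >= 0 && overlap < 1))
    stop("overlap must lie in [0, 1)", call. = FALSE)
  m <- min(vals); M <- max(vals)
  if (M - m <= 0 && n_intervals > 1L)
    stop("degenerate lens range: all values equal; use n_intervals = 1",
         call. = FALSE)
  len <- (M - m) / (n_intervals - (n_intervals - 1) * overlap)
  starts <- m + (seq_len(n_intervals) - 1L) * len * (1 - overlap)
  ends <- starts + len
  ends[n_intervals] <- M  # guard against round-off past the range
  structure(list(n_intervals = n_intervals, overlap = overlap,
                 intervals = cbind(start = starts, end = ends)),
            class = "mapper_cover")
}

#' @export
print.mapper_cover <- function(x, ...) {
  cat("Mapper cover:", x$n_intervals, "closed intervals, overlap",
      x$overlap, "\n")
  invisible(x)
}

#' Interval membership of lens values
#'
#' @param cover A `mapper_cover`.
#' @param values Numeric lens values.
#' @return A list, one integer vector of value indices per interval.
#' @export
cover_preimages <- function(cover, values) {
  lapply(seq_len(cover$n_intervals), function(k) {
    which(values >= cover$intervals[k, 1L] & values <= cover$intervals[k, 2L])
  })
}

#' Density-based clustering of a preimage
#'
#' DBSCAN on a precomputed correlation-distance submatrix: a point is a
#' core point if at least `min_samples` points (itself included) lie within
#' `eps`; clusters are the density-connected sets grown from core points;
#' remaining points are noise. DBSCAN is used because it does not fix the
#' number of clusters in advance and tolerates outliers. The result is
#' deterministic for a fixed input order.
#'
#' @param member_ids Character vector of ids to cluster (subset of
#'   `dmat$ids`).
#' @param dmat A `leaf_dist` distance matrix.
#' @param eps Neighborhood radius, in correlation-distance units.
#' @param min_samples Minimum neighborhood size for a core point.
#' @return A list with `clusters` (list of character vectors) and `noise`
#'   (character vector).
#' @export
cluster_preimage <- function(member_ids, dmat, eps, min_samples) {
  stopifnot(inherits(dmat, "leaf_dist"), eps > 0, min_samples >= 1)
  member_ids <- as.character(member_ids)
  if (length(member_ids) == 0L)
    return(list(clusters = list(), noise = character()))
  if (!all(member_ids %in% dmat$ids))
    stop("member_ids not all present in the distance matrix", call. = FALSE)
  d <- dmat$d[member_ids, member_ids, drop = FALSE]
  n <- length(member_ids)
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1L)) >= min_samples
  assignment <- rep.int(0L, n)   # 0 = unassigned, -1 = noise
  cluster_id <- 0L
  for (i in seq_len(n)) {
    if (assignment[i] != 0L || !core[i]) next
    cluster_id <- cluster_id + 1L
    assignment[i] <- cluster_id
    frontier <- nb[[i]]
    while (length(frontier)) {
      j <- frontier[1L]
      frontier <- frontier[-1L]
      if (assignment[j] == -1L) assignment[j] <- cluster_id  # border point
      if (assignment[j] != 0L) next
      assignment[j] <- cluster_id
      if (core[j]) frontier <- c(frontier, nb[[j]])
    }
  }
  assignment[assignment == 0L & !core] <- -1L
  clusters <- lapply(seq_len(cluster_id), function(k)
    member_ids[assignment == k])
  list(clusters = clusters, noise = member_ids[assignment == -1L])
}

#' Build a Mapper graph of a leaf dataset
#'
#' The Mapper construction: assign each leaf a lens value, cover the lens
#' range with overlapping intervals, cluster each interval's preimage under
#' the correlation distance with DBSCAN, and take the one-skeleton of the
#' nerve — one vertex per cluster, an edge wherever two clusters share a
#' leaf (possible because a leaf may fall in two overlapping intervals).
#' Vertices are annotated with their members, mean lens value, group-label
#' composition and mean shape.
#'
#' Distances are computed on the flattened raw landmark vectors by default;
#' set `align = TRUE` to superimpose with [gpa()] first. The cover and
#' clustering parameters are deliberately explicit: Mapper covers are
#' hand-tuned to taste, and every setting is recorded in the graph's
#' `params` for provenance.
#'
#' @param x A [leaf_dataset()].
#' @param lens `"pc1"`, `"heteroblasty"`, or a prebuilt `mapper_lens`.
#' @param n_intervals,overlap Cover parameters (see [build_cover()]).
#' @param eps,min_samples DBSCAN parameters (see [cluster_preimage()]).
#' @param align Superimpose leaves by GPA before computing distances.
#' @param distances Optional precomputed `leaf_dist` to reuse.
#' @return An object of class `mapper_graph`; see Details.
#' @details The returned object has `vertices` (list of records:
#'   `vertex_id` ("i<interval>_c<cluster>"), `interval_index`, `members`,
#'   `size`, `mean_lens`, `composition`, `mean_shape`), `edges` (data frame
#'   `from`, `to`, `weight` = shared-member count), `noise` (list of
#'   per-interval noise ids), and `params`.
#' @export
leaf_mapper <- function(x, lens = c("heteroblasty", "pc1"),
                        n_intervals = 12L, overlap = 0.35,
                        eps = 0.05, min_samples = 5L,
                        align = FALSE, distances = NULL) {
  stopifnot(inherits(x, "leaf_dataset"))
  if (align) x <- gpa(x)$aligned
  if (is.character(lens)) {
    lens <- match.arg(lens)
    lens <- switch(lens, heteroblasty = lens_heteroblasty(x),
                   pc1 = lens_pc1(x))
  }
  stopifnot(inherits(lens, "mapper_lens"))
  if (!identical(sort(lens$ids), sort(x$meta$leaf_id)))
    stop("lens ids do not match dataset leaf ids", call. = FALSE)
  if (is.null(distances)) distances <- pairwise_distances(x)
  vals <- lens$values[x$meta$leaf_id]
  cover <- build_cover(lens, n_intervals, overlap)
  labels <- stats::setNames(x$meta$group_label, x$meta$leaf_id)
  shapes <- flatten_leaves(x)

  preim <- cover_preimages(cover, vals)
  vertices <- list()
  noise <- vector("list", cover$n_intervals)
  names(noise) <- paste0("interval_", seq_len(cover$n_intervals))
  for (k in seq_len(cover$n_intervals)) {
    ids_k <- x$meta$leaf_id[preim[[k]]]
    res <- cluster_preimage(ids_k, distances, eps, min_samples)
    noise[[k]] <- res$noise
    if (!length(res$clusters)) next
    # deterministic cluster order: by each cluster's smallest member id
    ord <- order(vapply(res$clusters, function(m)
      min(match(m, x$meta$leaf_id)), numeric(1L)))
    for (ci in seq_along(ord)) {
      members <- res$clusters[[ord[ci]]]
      comp <- table(labels[members]) / length(members)
      vertices[[length(vertices) + 1L]] <- list(
        vertex_id = sprintf("i%d_c%d", k, ci),
        interval_index = k,
        members = members,
        size = length(members),
        mean_lens = mean(vals[members]),
        composition = stats::setNames(as.numeric(comp), names(comp)),
        mean_shape = matrix(colMeans(shapes[members, , drop = FALSE]),
                            ncol = 2L, byrow = TRUE,
                            dimnames = list(x$scheme$landmark_names,
                                            c("x", "y"))))
    }
  }
  graph <- nerve_edges(vertices)
  if (!length(vertices))
    warning("all points are noise: empty Mapper graph", call. = FALSE)
  structure(
    list(vertices = vertices, edges = graph, noise = noise,
         params = list(lens = lens$lens_name, n_intervals = n_intervals,
                       overlap = overlap, eps = eps,
                       min_samples = min_samples, align = align,
                       n_leaves = n_leaves(x),
                       cover = cover$intervals)),
    class = "mapper_graph")
}

# exhaustive pairwise-intersection edges over annotated vertices
nerve_edges <- function(vertices) {
  from <- character(); to <- character(); weight <- integer()
  nv <- length(vertices)
  if (nv >= 2L) {
    for (i in seq_len(nv - 1L)) {
      for (j in (i + 1L):nv) {
        shared <- length(intersect(vertices[[i]]$members,
                                   vertices[[j]]$members))
        if (shared > 0L) {
          from <- c(from, vertices[[i]]$vertex_id)
          to <- c(to, vertices[[j]]$vertex_id)
          weight <- c(weight, shared)
        }
      }
    }
  }
  data.frame(from = from, to = to, weight = weight,
             stringsAsFactors = FALSE)
}

#' Brute-force nerve construction (test oracle)
#'
#' Builds the one-skeleton of the nerve of a given clustering by exhaustive
#' pairwise intersection, with no shortcuts: an edge wherever two clusters
#' share a member. Intended as an independent reference for checking
#' [leaf_mapper()] on small inputs.
#'
#' @param clusters A list of records, each with `interval_index` and
#'   `members` (character vector).
#' @return A `mapper_graph` with membership annotations only.
#' @export
nerve_oracle <- function(clusters) {
  vertices <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    list(vertex_id = cl$vertex_id %||% sprintf("v%d", i),
         interval_index = cl$interval_index %||% NA_integer_,
         members = as.character(cl$members),
         size = length(cl$members),
         mean_lens = NA_real_, composition = NULL, mean_shape = NULL)
  })
  edges <- data.frame(from = character(), to = character(),
                      weight = integer(), stringsAsFactors = FALSE)
  nv <- length(vertices)
  if (nv >= 2L) {
    for (i in seq_len(nv - 1L)) for (j in (i + 1L):nv) {
      shared <- intersect(vertices[[i]]$members, vertices[[j]]$members)
      if (length(shared))
        edges <- rbind(edges, data.frame(
          from = vertices[[i]]$vertex_id, to = vertices[[j]]$vertex_id,
          weight = length(shared), stringsAsFactors = FALSE))
    }
  }
  structure(list(vertices = vertices, edges = edges, noise = list(),
                 params = list(lens = "oracle")),
            class = "mapper_graph")
}

#' @export
print.mapper_graph <- function(x, ...) {
  cat("Mapper graph (lens '", x$params$lens, "'): ",
      length(x$vertices), " vertices, ", nrow(x$edges), " edges\n", sep = "")
  nn <- length(unique(unlist(x$noise)))
  if (nn) cat("  noise points:", nn, "\n")
  invisible(x)
}

#' @export
summary.mapper_graph <- function(object, ...) {
  print(object)
  d <- graph_diagnostics(object)
  cat("  components:", d$n_components,
      " cycle rank b1:", d$cycle_rank, "\n")
  cat("  path-likeness:", sprintf("%.2f", d$path_likeness),
      " spine monotonicity:", sprintf("%.2f", d$spine_monotonicity), "\n")
  invisible(object)
}

#' Convert a Mapper graph to igraph
#'
#' @param graph A `mapper_graph`.
#' @return An [igraph::graph] with vertex attributes `interval`, `size`,
#'   `mean_lens`, and `composition` (JSON string).
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "mapper_graph"))
  ids <- vapply(graph$vertices, `[[`, character(1L), "vertex_id")
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  g <- igraph::set_vertex_attr(g, "interval", value =
    vapply(graph$vertices, function(v) as.integer(v$interval_index), integer(1L)))
  g <- igraph::set_vertex_attr(g, "size", value =
    vapply(graph$vertices, `[[`, integer(1L), "size"))
  g <- igraph::set_vertex_attr(g, "mean_lens", value =
    vapply(graph$vertices, function(v) as.numeric(v$mean_lens), numeric(1L)))
  g <- igraph::set_vertex_attr(g, "composition", value =
    vapply(graph$vertices, function(v)
      as.character(jsonlite::toJSON(as.list(v$composition %||% list()),
                                    auto_unbox = TRUE, digits = NA)),
      character(1L)))
  g <- igraph::set_vertex_attr(g, "mean_shape", value =
    vapply(graph$vertices, function(v)
      if (is.null(v$mean_shape)) "" else
        paste(sprintf("%.10g", as.vector(t(v$mean_shape))), collapse = " "),
      character(1L)))
  if (nrow(graph$edges)) {
    g <- igraph::add_edges(g, rbind(match(graph$edges$from, ids),
                                    match(graph$edges$to, ids)))
    g <- igraph::set_edge_attr(g, "weight", value = graph$edges$weight)
  }
  g
}

#' Structural diagnostics of a Mapper graph
#'
#' Quantifies the qualitative reading of a Mapper graph: a conserved
#' developmental program shows up as a path-like "central spine" whose
#' vertex mean lens values increase monotonically, while branch-and-rejoin
#' deviations (the "reverse hourglass") add independent cycles.
#'
#' @param graph A `mapper_graph`.
#' @return A list: `n_vertices`, `n_edges`, `n_components` (C), `cycle_rank`
#'   (first Betti number, `|E| - |V| + C`), `path_likeness` (fraction of
#'   vertices with degree <= 2), `spine` (vertex ids along the spine — the
#'   longest shortest path of the largest component, oriented so mean lens
#'   ascends), `spine_monotonicity` (Spearman correlation of position along
#'   the spine with vertex mean lens), and `empty` flag.
#' @export
graph_diagnostics <- function(graph) {
  stopifnot(inherits(graph, "mapper_graph"))
  nv <- length(graph$vertices)
  if (nv == 0L)
    return(list(n_vertices = 0L, n_edges = 0L, n_components = 0L,
                cycle_rank = 0L, path_likeness = 0, spine = character(),
                spine_monotonicity = 0, empty = TRUE))
  g <- as_igraph(graph)
  ne <- nrow(graph$edges)
  comp <- igraph::components(g)
  C <- comp$no
  b1 <- ne - nv + C
  deg <- igraph::degree(g)
  path_likeness <- mean(deg <= 2L)
  # spine: diameter path of the largest component, lens-ascending
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  spine <- igraph::get_diameter(sub, weights = NA)$name
  ml <- igraph::vertex_attr(sub, "mean_lens",
                            match(spine, igraph::V(sub)$name))
  if (anyNA(ml)) {
    mono <- NA_real_
  } else {
    if (length(spine) >= 2L && ml[length(ml)] < ml[1L]) {
      spine <- rev(spine); ml <- rev(ml)
    }
    mono <- if (length(spine) < 2L || stats::sd(ml) == 0) 1 else
      suppressWarnings(stats::cor(seq_along(ml), ml, method = "spearman"))
  }
  list(n_vertices = nv, n_edges = ne, n_components = C,
       cycle_rank = as.integer(b1), path_likeness = path_likeness,
       spine = spine, spine_monotonicity = mono, empty = FALSE)
}

#' Vertices off the central spine
#'
#' @param graph A `mapper_graph`.
#' @return Character vector of vertex ids not on the spine identified by
#'   [graph_diagnostics()] — the branching structure.
#' @export
off_spine_vertices <- function(graph) {
  d <- graph_diagnostics(graph)
  ids <- vapply(graph$vertices, `[[`, character(1L), "vertex_id")
  setdiff(ids, d$spine)
}

#' Majority group label of each vertex
#'
#' @param graph A `mapper_graph`.
#' @return Named character vector: for each vertex, the group label holding
#'   the largest composition share.
#' @export
vertex_majority_label <- function(graph) {
  out <- vapply(graph$vertices, function(v) {
    if (is.null(v$composition) || !length(v$composition)) return(NA_character_)
    names(v$composition)[which.max(v$composition)]
  }, character(1L))
  names(out) <- vapply(graph$vertices, `[[`, character(1L), "vertex_id")
  out
}
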