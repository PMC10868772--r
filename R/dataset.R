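#' Leaf dataset container
#'
#' A `leaf_dataset` bundles a landmark scheme, a metadata table (one row per
#' leaf: `leaf_id`, `group_label`, `vine_id`, `node_index`, `relative_node`)
#' and a coordinate matrix with one row per leaf and columns
#' `x1, y1, ..., xn, yn` in landmark order. `node_index` counts from the
#' growing tip of the vine; `relative_node` is the heteroblasty value in
#' [0, 1] (0 = growing tip, 1 = shoot base), `NA` until assigned by
#' [assign_relative_node()]. Leaves are kept in a deterministic order:
#' sorted by `vine_id`, `node_index`, `leaf_id`.
#'
#' @param scheme A [landmark_scheme()].
#' @param meta Data frame with columns `leaf_id`, `group_label`, `vine_id`,
#'   `node_index` and optionally `relative_node`.
#' @param coords Numeric matrix, `nrow(meta)` rows by `2 * n_landmarks`
#'   columns, coordinates interleaved x1, y1, x2, y2, ...
#' @param provenance Free-text provenance string.
#' @return An object of class `leaf_dataset`.
#' @export
leaf_dataset <- function(scheme, meta, coords, provenance = "") {
  if (!inherits(scheme, "landmark_scheme"))
    stop("scheme must be a landmark_scheme", call. = FALSE)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("leaf_id", "group_label", "vine_id", "node_index")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"relative_node" %in% names(meta))
    meta$relative_node <- rep(NA_real_, nrow(meta))
  meta$leaf_id <- as.character(meta$leaf_id)
  meta$group_label <- as.character(meta$group_label)
  meta$vine_id <- as.character(meta$vine_id)
  meta$node_index <- as.integer(meta$node_index)
  meta$relative_node <- as.numeric(meta$relative_node)
  meta <- meta[, c(required, "relative_node")]

  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != nrow(meta))
    stop("coords and meta row counts differ", call. = FALSE)
  if (ncol(coords) != 2L * scheme$n_landmarks)
    stop("coords must have ", 2L * scheme$n_landmarks,
         " columns for scheme '", scheme$name, "'", call. = FALSE)
  if (nrow(coords) > 0L && !all(is.finite(coords)))
    stop("all landmark coordinates must be finite", call. = FALSE)
  if (anyDuplicated(meta$leaf_id))
    stop("duplicate leaf_id: ",
         paste(unique(meta$leaf_id[duplicated(meta$leaf_id)]),
               collapse = ", "), call. = FALSE)
  bad_rel <- !is.na(meta$relative_node) &
    (meta$relative_node < 0 | meta$relative_node > 1)
  if (any(bad_rel))
    stop("relative_node values must lie in [0, 1]", call. = FALSE)

  ord <- order(meta$vine_id, meta$node_index, meta$leaf_id)
  meta <- meta[ord, , drop = FALSE]
  coords <- coords[ord, , drop = FALSE]
  rownames(meta) <- NULL
  rownames(coords) <- meta$leaf_id
  colnames(coords) <- coordinate_columns(scheme)

  structure(
    list(scheme = scheme, meta = meta, coords = coords,
         provenance = provenance),
    class = "leaf_dataset")
}

#' @export
print.leaf_dataset <- function(x, ...) {
  cat("Leaf dataset: ", nrow(x$meta), " leaves, scheme '", x$scheme$name,
      "' (", x$scheme$n_landmarks, " landmarks)\n", sep = "")
  if (nrow(x$meta)) {
    cat("  groups: ", paste(sort(unique(x$meta$group_label)),
                            collapse = ", "), "\n", sep = "")
    cat("  vines:  ", length(unique(x$meta$vine_id)), "\n", sep = "")
    if (all(is.na(x$meta$relative_node)))
      cat("  relative_node: unassigned\n")
    else
      cat("  relative_node: [",
          format(min(x$meta$relative_node, na.rm = TRUE)), ", ",
          format(max(x$meta$relative_node, na.rm = TRUE)), "]\n", sep = "")
  }
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @export
summary.leaf_dataset <- function(object, ...) {
  print(object)
  if (nrow(object$meta)) {
    cat("\nLeaves per group:\n")
    print(table(object$meta$group_label))
  }
  invisible(object)
}

#' Number of leaves
#' @param x A `leaf_dataset`.
#' @return Integer count of leaves.
#' @export
n_leaves <- function(x) {
  stopifnot(inherits(x, "leaf_dataset"))
  nrow(x$meta)
}

#' Landmark matrix of one leaf
#'
#' @param x A `leaf_dataset`.
#' @param leaf Leaf id (character) or row index.
#' @return An `n_landmarks` x 2 matrix with columns `x`, `y`.
#' @export
leaf_landmarks <- function(x, leaf) {
  stopifnot(inherits(x, "leaf_dataset"))
  if (is.character(leaf)) {
    i <- match(leaf, x$meta$leaf_id)
    if (is.na(i)) stop("unknown leaf_id: ", leaf, call. = FALSE)
  } else i <- leaf
  v <- x$coords[i, ]
  matrix(v, ncol = 2L, byrow = TRUE,
         dimnames = list(x$scheme$landmark_names, c("x", "y")))
}

#' Subset a leaf dataset by leaf
#'
#' @param x A `leaf_dataset`.
#' @param i Logical, integer, or character (leaf ids) index over leaves.
#' @param ... Unused.
#' @return A `leaf_dataset` with the selected leaves.
#' @export
`[.leaf_dataset` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$meta$leaf_id)
  leaf_dataset(x$scheme, x$meta[i, , drop = FALSE],
               x$coords[i, , drop = FALSE], x$provenance)
}

set_coords <- function(x, coords) {
  # internal: replace coordinates, preserving metadata and order
  stopifnot(identical(dim(coords), dim(x$coords)))
  x$coords <- coords
  dimnames(x$coords) <- list(x$meta$leaf_id, coordinate_columns(x$scheme))
  x
}

#' Plot leaves of a dataset
#'
#' Draws each leaf's landmark polygon, optionally colored by group label or
#' by relative node position.
#'
#' @param x A `leaf_dataset`.
#' @param color_by `"group"` or `"heteroblasty"`.
#' @param max_leaves Draw at most this many leaves (evenly subsampled).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.leaf_dataset <- function(x, color_by = c("group", "heteroblasty"),
                              max_leaves = 100L, ...) {
  color_by <- match.arg(color_by)
  n <- n_leaves(x)
  if (n == 0L) stop("empty dataset", call. = FALSE)
  keep <- if (n > max_leaves) unique(round(seq(1L, n, length.out = max_leaves))) else seq_len(n)
  if (color_by == "group") {
    groups <- sort(unique(x$meta$group_label))
    pal <- grDevices::hcl.colors(max(length(groups), 2L), "Dark 3")
    col <- pal[match(x$meta$group_label, groups)]
  } else {
    rn <- x$meta$relative_node
    if (all(is.na(rn))) stop("relative_node unassigned", call. = FALSE)
    pal <- grDevices::hcl.colors(101L, "Viridis")
    col <- pal[1L + round(100 * rn)]
  }
  xs <- x$coords[keep, seq(1L, ncol(x$coords), by = 2L), drop = FALSE]
  ys <- x$coords[keep, seq(2L, ncol(x$coords), by = 2L), drop = FALSE]
  graphics::plot(range(xs), range(ys), type = "n", asp = 1,
                 xlab = "x", ylab = "y", ...)
  for (k in seq_along(keep)) {
    graphics::polygon(xs[k, ], ys[k, ], border = col[keep[k]], lwd = 0.8)
  }
  invisible(x)
}

#' Flatten leaves to shape vectors
#'
#' Each leaf becomes a row vector `(x1, y1, x2, y2, ..., xn, yn)` of length
#' `2 * n_landmarks` — e.g. 30 for the 15-landmark grapevine scheme. This is
#' the point-cloud representation used for distances, lenses and ordination.
#'
#' @param x A `leaf_dataset`.
#' @return Numeric matrix, one row per leaf (rownames = leaf ids).
#' @export
flatten_leaves <- function(x) {
  stopifnot(inherits(x, "leaf_dataset"))
  x$coords
}

#' @export
as.data.frame.leaf_dataset <- function(x, ...) {
  cbind(x$meta, as.data.frame(x$coords, row.names = NULL))
}
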