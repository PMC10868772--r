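#' Assign relative node (heteroblasty) positions
#'
#' For each vine, leaves are ranked by `node_index` (counted from the
#' growing tip) and assigned `relative_node = (rank - 1) / (N - 1)`, so the
#' tip-most leaf gets 0 and the base-most leaf gets 1. Ranks — not raw node
#' indices — are used, so vines with missing nodes still span [0, 1].
#' Vines with a single leaf are dropped with a warning (the denominator
#' N - 1 is undefined for them).
#'
#' @param x A [leaf_dataset()] in which every leaf has `vine_id` and
#'   `node_index`.
#' @return A new `leaf_dataset` with `relative_node` filled in; the input is
#'   unchanged.
#' @export
assign_relative_node <- function(x) {
  stopifnot(inherits(x, "leaf_dataset"))
  meta <- x$meta
  key <- paste(meta$vine_id, meta$node_index, sep = "\r")
  if (anyDuplicated(key))
    stop("integrity error: duplicate (vine_id, node_index) pair(s): ",
         paste(unique(gsub("\r", ":", key[duplicated(key)])),
               collapse = ", "), call. = FALSE)
  sizes <- table(meta$vine_id)
  singletons <- names(sizes)[sizes < 2L]
  if (length(singletons) == length(sizes) && length(sizes) > 0L)
    stop("no vine has two or more leaves; relative node undefined",
         call. = FALSE)
  if (length(singletons)) {
    warning("excluding ", length(singletons),
            " single-leaf vine(s): ", paste(singletons, collapse = ", "),
            call. = FALSE)
    keep <- !(meta$vine_id %in% singletons)
    x <- x[which(keep)]
    meta <- x$meta
  }
  rel <- numeric(nrow(meta))
  for (v in unique(meta$vine_id)) {
    idx <- which(meta$vine_id == v)
    rk <- rank(meta$node_index[idx])
    rel[idx] <- (rk - 1) / (length(idx) - 1)
  }
  x$meta$relative_node <- rel
  x
}

#' Subset to a shared landmark selection
#'
#' Restricts every leaf to the given landmark indices, in selection order,
#' and replaces the scheme with the derived one. Used to reduce the
#' genus-specific schemes to the six landmarks both genera share before
#' building a common morphospace.
#'
#' @param x A `leaf_dataset`.
#' @param selection Integer vector of distinct landmark indices (1-based),
#'   or a [landmark_scheme()] to carry names/axis over (must have
#'   `length(selection)` landmarks).
#' @param scheme Optional replacement [landmark_scheme()] for the subset;
#'   by default a derived scheme keeping the selected landmark names.
#' @return A `leaf_dataset` on the reduced scheme.
#' @export
subset_shared_landmarks <- function(x, selection, scheme = NULL) {
  stopifnot(inherits(x, "leaf_dataset"))
  selection <- as.integer(selection)
  if (length(selection) == 0L)
    stop("empty landmark selection is not allowed", call. = FALSE)
  if (anyDuplicated(selection))
    stop("landmark selection must be distinct", call. = FALSE)
  if (any(selection < 1L | selection > x$scheme$n_landmarks))
    stop("index error: landmark selection out of range 1..",
         x$scheme$n_landmarks, call. = FALSE)
  if (is.null(scheme)) {
    scheme <- landmark_scheme(
      paste0(x$scheme$name, "_subset"),
      x$scheme$landmark_names[selection])
  }
  if (scheme$n_landmarks != length(selection))
    stop("replacement scheme size does not match selection", call. = FALSE)
  cols <- as.vector(rbind(2L * selection - 1L, 2L * selection))
  leaf_dataset(scheme, x$meta, x$coords[, cols, drop = FALSE], x$provenance)
}

#' Reflect landmarks across the leaf midline to complete a half leaf
#'
#' Grapevine leaves are digitized on one side only; to compare them with
#' fully sampled leaves, every non-axis landmark is mirrored across the line
#' through the two axis landmarks (petiolar-junction base and leaf tip) and
#' appended, in original order. Axis landmarks are kept once, so a leaf with
#' n landmarks becomes one with `n + (n - 2)`.
#'
#' @param x A `leaf_dataset` (all leaves completed) or a single-leaf matrix.
#' @param axis_indices Integer pair of axis landmark indices; defaults to
#'   the scheme's `axis_indices`.
#' @return A `leaf_dataset` on the derived completed scheme.
#' @export
reflect_to_complete <- function(x, axis_indices = NULL) {
  stopifnot(inherits(x, "leaf_dataset"))
  axis_indices <- axis_indices %||% x$scheme$axis_indices
  if (is.null(axis_indices))
    stop("scheme has no axis_indices and none were given", call. = FALSE)
  axis_indices <- as.integer(axis_indices)
  n <- x$scheme$n_landmarks
  if (length(axis_indices) != 2L || anyDuplicated(axis_indices) ||
      any(axis_indices < 1L | axis_indices > n))
    stop("axis_indices must be two distinct valid landmark indices",
         call. = FALSE)
  off_axis <- setdiff(seq_len(n), axis_indices)
  new_names <- c(x$scheme$landmark_names,
                 paste0(x$scheme$landmark_names[off_axis], "_reflected"))
  scheme <- landmark_scheme(paste0(x$scheme$name, "_completed"), new_names,
                            axis_indices = axis_indices)
  out <- matrix(NA_real_, n_leaves(x), 2L * scheme$n_landmarks)
  for (i in seq_len(n_leaves(x))) {
    lm <- leaf_landmarks(x, i)
    mirrored <- reflect_points(lm[off_axis, , drop = FALSE],
                               lm[axis_indices[1L], ], lm[axis_indices[2L], ])
    full <- rbind(lm, mirrored)
    out[i, ] <- as.vector(t(full))
  }
  leaf_dataset(scheme, x$meta, out, x$provenance)
}

# Mirror points across the line through a and b. Geometry error if a == b.
reflect_points <- function(p, a, b) {
  d <- b - a
  nd <- sum(d^2)
  if (nd < .Machine$double.eps)
    stop("geometry error: coincident axis landmarks", call. = FALSE)
  u <- d / sqrt(nd)
  # reflection of q: a + (2 u u' - I) (q - a)
  R <- 2 * tcrossprod(u) - diag(2)
  sweep(sweep(p, 2L, a) %*% t(R), 2L, a, `+`)
}

#' Split a dataset at a relative-node threshold
#'
#' Partitions leaves into the growing-tip part (`relative_node <= threshold`,
#' under the 0 = tip convention) and the shoot-base part
#' (`relative_node > threshold`). A boundary leaf goes to the tip part.
#'
#' @param x A `leaf_dataset` with `relative_node` assigned.
#' @param threshold Split point in (0, 1); default 0.5.
#' @return A list with elements `base` and `tip`, both `leaf_dataset`s that
#'   together partition `x`.
#' @export
split_by_position <- function(x, threshold = 0.5) {
  stopifnot(inherits(x, "leaf_dataset"))
  if (!(threshold > 0 && threshold < 1))
    stop("threshold must lie strictly between 0 and 1", call. = FALSE)
  rn <- x$meta$relative_node
  if (anyNA(rn) && n_leaves(x) > 0L)
    stop("state error: relative_node unassigned; run assign_relative_node()",
         call. = FALSE)
  tip_idx <- which(rn <= threshold)
  base_idx <- which(rn > threshold)
  list(base = x[base_idx], tip = x[tip_idx])
}

#' Split leaves into ontogenetic and heteroblastic series per vine
#'
#' For each vine, leaves whose relative node value is at most the vine's
#' mean relative node are assigned to the ontogenetic series (near the
#' growing tip, where individual leaves are still expanding); leaves above
#' the mean form the heteroblastic series (mature leaves whose differences
#' reflect node position).
#'
#' @param x A `leaf_dataset` with `relative_node` assigned.
#' @return A list with elements `heteroblastic` and `ontogenetic`, two
#'   `leaf_dataset`s partitioning `x`.
#' @export
split_by_vine_mean <- function(x) {
  stopifnot(inherits(x, "leaf_dataset"))
  rn <- x$meta$relative_node
  if (anyNA(rn) && n_leaves(x) > 0L)
    stop("state error: relative_node unassigned; run assign_relative_node()",
         call. = FALSE)
  onto <- logical(n_leaves(x))
  for (v in unique(x$meta$vine_id)) {
    idx <- which(x$meta$vine_id == v)
    onto[idx] <- rn[idx] <= mean(rn[idx])
  }
  list(heteroblastic = x[which(!onto)], ontogenetic = x[which(onto)])
}
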