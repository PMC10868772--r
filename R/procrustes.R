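#' Center a landmark configuration and scale it to unit centroid size
#'
#' Centroid size is the root summed squared distance of the landmarks to
#' their centroid; Procrustes superimposition removes location and scale by
#' translating the centroid to the origin and dividing by centroid size.
#'
#' @param p An n x 2 landmark matrix.
#' @return The normalized n x 2 matrix.
#' @export
normalize_shape <- function(p) {
  p <- sweep(p, 2L, colMeans(p))
  cs <- sqrt(sum(p^2))
  if (cs < .Machine$double.eps)
    stop("geometry error: degenerate shape (all landmarks coincident)",
         call. = FALSE)
  p / cs
}

centroid_size <- function(p) sqrt(sum(sweep(p, 2L, colMeans(p))^2))

# Rotation taking a centered configuration to principal-axis orientation,
# with a deterministic sign: the largest-|loading| coordinate on each axis
# is positive (second axis sign constrained to keep det = +1).
canonical_rotation <- function(ms) {
  e <- eigen(crossprod(ms), symmetric = TRUE)
  R <- e$vectors
  if (det(R) < 0) R[, 2L] <- -R[, 2L]
  m2 <- ms %*% R
  i <- which.max(abs(m2[, 1L]))
  if (m2[i, 1L] < 0) R <- -R   # half-turn keeps det = +1
  R
}

# Optimal rotation of normalized shape b onto normalized shape a.
# Proper rotation (det +1) unless allow_reflection.
optimal_rotation <- function(a, b, allow_reflection = FALSE) {
  s <- svd(crossprod(b, a))
  R <- s$u %*% t(s$v)
  if (!allow_reflection && det(R) < 0) {
    u <- s$u
    u[, 2L] <- -u[, 2L]
    R <- u %*% t(s$v)
  }
  R
}

#' Pairwise Procrustes superimposition
#'
#' Centers and scales both configurations to unit centroid size, then
#' rotates the target onto the reference to minimize the summed squared
#' landmark distance. Rotations are proper by default: mirror-image leaves
#' are never flipped implicitly (handedness is biologically meaningful;
#' use [reflect_to_complete()] for explicit reflection).
#'
#' @param reference,target n x 2 landmark matrices (n >= 2, same n).
#' @param allow_reflection Permit an improper (reflecting) orthogonal map.
#' @return A list with `reference` and `aligned_target` (both normalized,
#'   target rotated), `rotation` (2 x 2), and `disparity` — the minimized
#'   summed squared distance.
#' @export
procrustes_pair <- function(reference, target, allow_reflection = FALSE) {
  reference <- as.matrix(reference); target <- as.matrix(target)
  if (!identical(dim(reference), dim(target)) || nrow(reference) < 2L)
    stop("reference and target must be equal-size landmark matrices with >= 2 landmarks",
         call. = FALSE)
  a <- normalize_shape(reference)
  b <- normalize_shape(target)
  R <- optimal_rotation(a, b, allow_reflection)
  bR <- b %*% R
  list(reference = a, aligned_target = bR, rotation = R,
       disparity = sum((a - bR)^2))
}

#' Generalized Procrustes analysis
#'
#' Iteratively superimposes all leaves of a dataset: every configuration is
#' centered and scaled to unit centroid size, rotated onto the current mean
#' shape, and the mean is recomputed and renormalized, until the mean
#' changes by less than `tol` (root summed squared difference) or
#' `max_iter` is reached. The initial mean is the first leaf after
#' normalization, so the result is deterministic for a fixed dataset order.
#' The converged configuration is reported in a canonical orientation
#' (principal axes of the mean shape, deterministic sign), so the output is
#' invariant under any common similarity transform of the input leaves.
#'
#' @param x A [leaf_dataset()] (>= 1 leaf, no degenerate shapes).
#' @param tol Convergence tolerance on the mean-shape change.
#' @param max_iter Iteration cap; non-convergence warns but still returns.
#' @param allow_reflection Permit improper rotations during fitting.
#' @return An object of class `leaf_gpa`: a list with `aligned` (the
#'   dataset with superimposed coordinates), `mean_shape` (n x 2, centered,
#'   unit centroid size), `iterations`, `final_change` and `converged`.
#' @export
gpa <- function(x, tol = 1e-7, max_iter = 100L, allow_reflection = FALSE) {
  stopifnot(inherits(x, "leaf_dataset"))
  m <- n_leaves(x)
  if (m < 1L) stop("gpa needs at least one leaf", call. = FALSE)
  shapes <- lapply(seq_len(m), function(i) normalize_shape(leaf_landmarks(x, i)))
  mean_shape <- shapes[[1L]]
  rotated <- shapes
  iterations <- 0L
  final_change <- Inf
  repeat {
    iterations <- iterations + 1L
    rotated <- lapply(shapes, function(s)
      s %*% optimal_rotation(mean_shape, s, allow_reflection))
    new_mean <- normalize_shape(Reduce(`+`, rotated) / m)
    final_change <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (final_change < tol || iterations >= max_iter) break
  }
  converged <- final_change < tol
  if (!converged)
    warning("gpa did not converge in ", max_iter,
            " iterations (final change ", format(final_change), ")",
            call. = FALSE)
  # final rotation pass against the converged mean
  rotated <- lapply(shapes, function(s)
    s %*% optimal_rotation(mean_shape, s, allow_reflection))
  # canonicalize the global orientation (GPA is defined only up to one
  # overall rotation): principal axes of the mean, sign fixed by the
  # largest-magnitude loading — so equal datasets in different poses give
  # identical aligned coordinates
  Rc <- canonical_rotation(mean_shape)
  mean_shape <- mean_shape %*% Rc
  rotated <- lapply(rotated, function(s) s %*% Rc)
  coords <- do.call(rbind, lapply(rotated, function(s) as.vector(t(s))))
  aligned <- set_coords(x, coords)
  dimnames(mean_shape) <- list(x$scheme$landmark_names, c("x", "y"))
  structure(
    list(aligned = aligned, mean_shape = mean_shape,
         iterations = iterations, final_change = final_change,
         converged = converged, tol = tol),
    class = "leaf_gpa")
}

#' @export
print.leaf_gpa <- function(x, ...) {
  cat("Generalized Procrustes alignment of", n_leaves(x$aligned), "leaves\n")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  final mean-shape change:", format(x$final_change), "\n")
  invisible(x)
}

#' Procrustes residuals
#'
#' @param object A `leaf_gpa` fit.
#' @param ... Unused.
#' @return Numeric vector: each leaf's summed squared deviation from the
#'   mean shape (its Procrustes disparity to the consensus).
#' @export
residuals.leaf_gpa <- function(object, ...) {
  mv <- as.vector(t(object$mean_shape))
  res <- apply(flatten_leaves(object$aligned), 1L,
               function(v) sum((v - mv)^2))
  res
}

#' Plot a GPA fit
#'
#' Overlays the aligned leaves (grey) on the consensus mean shape.
#'
#' @param x A `leaf_gpa` fit.
#' @param max_leaves Cap on the number of leaves drawn.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.leaf_gpa <- function(x, max_leaves = 100L, ...) {
  plot(x$aligned, max_leaves = max_leaves, ...)
  graphics::polygon(x$mean_shape[, 1L], x$mean_shape[, 2L], border = "black",
                    lwd = 2)
  invisible(x)
}

#' Serialize a GPA fit
#'
#' Writes the aligned coordinates in the standard landmark CSV layout and,
#' optionally, the mean shape plus convergence metadata as JSON.
#'
#' @param x A `leaf_gpa` fit.
#' @param csv_path Path for the aligned-coordinate CSV (or `NULL` to skip).
#' @param json_path Path for the JSON metadata (or `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_gpa <- function(x, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(x, "leaf_gpa"))
  if (!is.null(csv_path)) write_landmark_table(x$aligned, csv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(mean_shape = unname(x$mean_shape), iterations = x$iterations,
           final_change = x$final_change, converged = x$converged),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csv = csv_path, json = json_path))
}
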