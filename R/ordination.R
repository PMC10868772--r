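#' Principal component analysis of shape vectors
#'
#' Fits a PCA to flattened landmark vectors (rows of a matrix, or a
#' [leaf_dataset()]). Built on [stats::prcomp()] with a deterministic sign
#' convention: each component is flipped, if necessary, so that its
#' largest-magnitude loading is positive. PCA signs are otherwise
#' arbitrary, and the first component doubles as a Mapper lens, so
#' reproducible orientation matters.
#'
#' @param x Numeric matrix of shape vectors (rows = leaves) or a
#'   `leaf_dataset`.
#' @param n_components Number of components to keep; default all
#'   (`min(n - 1, 2p)`).
#' @return An object of class `shape_pca`: `mean_vector`, `components`
#'   (columns, orthonormal), `explained_variance` (non-increasing),
#'   `total_variance`.
#' @export
shape_pca <- function(x, n_components = NULL) {
  v <- if (inherits(x, "leaf_dataset")) flatten_leaves(x) else as.matrix(x)
  if (nrow(v) < 2L)
    stop("insufficient data: PCA needs at least 2 shape vectors",
         call. = FALSE)
  k_max <- min(nrow(v) - 1L, ncol(v))
  n_components <- as.integer(n_components %||% k_max)
  if (n_components < 1L || n_components > k_max)
    stop("n_components must lie in 1..", k_max, call. = FALSE)
  fit <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  comp <- fit$rotation[, seq_len(n_components), drop = FALSE]
  # deterministic orientation: largest-|loading| entry positive
  for (j in seq_len(ncol(comp))) {
    i <- which.max(abs(comp[, j]))
    if (comp[i, j] < 0) comp[, j] <- -comp[, j]
  }
  structure(
    list(mean_vector = fit$center,
         components = comp,
         explained_variance = fit$sdev[seq_len(n_components)]^2,
         total_variance = sum(fit$sdev^2),
         n_obs = nrow(v)),
    class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  k <- length(x$explained_variance)
  cat("Shape PCA:", k, "components over", length(x$mean_vector),
      "coordinates (", x$n_obs, "leaves )\n")
  pct <- 100 * x$explained_variance / x$total_variance
  cat("  variance explained:",
      paste0(sprintf("PC%d %.1f%%", seq_len(min(k, 5L)), pct[seq_len(min(k, 5L))]),
             collapse = ", "),
      if (k > 5L) "..." else "", "\n")
  invisible(x)
}

#' Project shape vectors into PCA space
#'
#' @param model A `shape_pca`.
#' @param v A shape vector or matrix of row vectors.
#' @return Score matrix (rows = inputs, columns = components).
#' @export
pca_scores <- function(model, v) {
  stopifnot(inherits(model, "shape_pca"))
  v <- if (is.null(dim(v))) matrix(v, nrow = 1L) else as.matrix(v)
  if (ncol(v) != length(model$mean_vector))
    stop("dimension error: vectors have ", ncol(v), " coordinates, model has ",
         length(model$mean_vector), call. = FALSE)
  sweep(v, 2L, model$mean_vector) %*% model$components
}

#' Reconstruct shape vectors from PCA scores
#'
#' The inverse transform: `mean + sum(score_i * component_i)`. With all
#' components retained this inverts [pca_scores()] exactly.
#'
#' @param model A `shape_pca`.
#' @param scores Score vector or matrix (columns = leading components; may
#'   be fewer than the model holds, remaining scores taken as zero).
#' @return Matrix of reconstructed shape vectors.
#' @export
pca_inverse <- function(model, scores) {
  stopifnot(inherits(model, "shape_pca"))
  scores <- if (is.null(dim(scores))) matrix(scores, nrow = 1L) else
    as.matrix(scores)
  k <- ncol(scores)
  if (k > ncol(model$components))
    stop("dimension error: ", k, " scores but model holds ",
         ncol(model$components), " components", call. = FALSE)
  sweep(scores %*% t(model$components[, seq_len(k), drop = FALSE]),
        2L, model$mean_vector, `+`)
}

#' Reconstruct a morphospace grid of shapes
#'
#' Evaluates the PCA inverse transform on a grid of score pairs over two
#' chosen components (zeros elsewhere), yielding the theoretical leaf
#' shapes tiling that plane of the morphospace.
#'
#' @param model A `shape_pca`.
#' @param pc_indices Integer pair of component indices.
#' @param grid Two-column matrix (or list of pairs) of scores for the two
#'   components.
#' @return A list of n x 2 landmark matrices, one per grid point.
#' @export
morphospace_grid <- function(model, pc_indices = c(1L, 2L), grid) {
  stopifnot(inherits(model, "shape_pca"))
  pc_indices <- as.integer(pc_indices)
  if (length(pc_indices) != 2L ||
      any(pc_indices < 1L | pc_indices > ncol(model$components)))
    stop("pc_indices must be two valid component indices", call. = FALSE)
  if (is.list(grid)) grid <- do.call(rbind, lapply(grid, as.numeric))
  grid <- as.matrix(grid)
  scores <- matrix(0, nrow(grid), ncol(model$components))
  scores[, pc_indices[1L]] <- grid[, 1L]
  scores[, pc_indices[2L]] <- grid[, 2L]
  recon <- pca_inverse(model, scores)
  lapply(seq_len(nrow(recon)), function(i)
    matrix(recon[i, ], ncol = 2L, byrow = TRUE,
           dimnames = list(NULL, c("x", "y"))))
}

#' Linear discriminant analysis of labeled shape vectors
#'
#' Fisher's discriminant: axes maximizing the ratio of between-class to
#' within-class scatter, found by the generalized eigenproblem on the two
#' scatter matrices. At most `n_classes - 1` axes are kept. If the
#' within-class scatter is singular (possible when coordinates outnumber
#' leaves) a small ridge `1e-6 * trace / p` is added with a warning. Axes
#' follow the same deterministic sign convention as [shape_pca()].
#' Classification is by nearest class mean in discriminant space.
#'
#' @param x Numeric matrix of shape vectors (rows) or a `leaf_dataset`
#'   (whose `group_label` supplies missing `labels`).
#' @param labels Character vector of class labels, one per row.
#' @return An object of class `shape_lda`: `class_labels`,
#'   `discriminant_axes` (columns), `class_means` (rows, in discriminant
#'   space), `mean_vector`, plus training `scores` and `accuracy`.
#' @export
shape_lda <- function(x, labels = NULL) {
  v <- if (inherits(x, "leaf_dataset")) flatten_leaves(x) else as.matrix(x)
  if (is.null(labels) && inherits(x, "leaf_dataset"))
    labels <- x$meta$group_label
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(v))
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop("insufficient data: LDA needs at least 2 classes", call. = FALSE)
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2L))
    stop("insufficient data: every class needs >= 2 members (",
         paste(names(counts)[counts < 2L], collapse = ", "), ")",
         call. = FALSE)
  p <- ncol(v)
  grand <- colMeans(v)
  Sw <- matrix(0, p, p)
  Sb <- matrix(0, p, p)
  for (cl in classes) {
    rows <- v[labels == cl, , drop = FALSE]
    mu <- colMeans(rows)
    cen <- sweep(rows, 2L, mu)
    Sw <- Sw + crossprod(cen)
    Sb <- Sb + nrow(rows) * tcrossprod(mu - grand)
  }
  # ridge-regularize a (near-)singular within-class scatter; fall back to
  # the between-class scale when the within scatter is identically zero
  if (rcond_sym(Sw) < 1e-12) {
    warning("within-class scatter is singular; applying ridge regularization",
            call. = FALSE)
    lam <- 1e-6 * sum(diag(Sw)) / p
    if (lam <= 0) lam <- 1e-8 * max(sum(diag(Sb)) / p, 1)
    Sw <- Sw + diag(lam, p)
  }
  # solve Sw^{-1} Sb via symmetric whitening for stable real eigenvectors
  es <- eigen(Sw, symmetric = TRUE)
  ev <- pmax(es$values, max(es$values) * 1e-12)
  W <- es$vectors %*% diag(1 / sqrt(ev), p) %*% t(es$vectors)
  M <- W %*% Sb %*% W
  eb <- eigen((M + t(M)) / 2, symmetric = TRUE)
  k <- min(length(classes) - 1L, p)
  axes <- W %*% eb$vectors[, seq_len(k), drop = FALSE]
  axes <- apply(axes, 2L, function(a) a / sqrt(sum(a^2)))
  axes <- matrix(axes, nrow = p)
  for (j in seq_len(ncol(axes))) {
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  colnames(axes) <- paste0("LD", seq_len(k))
  scores <- sweep(v, 2L, grand) %*% axes
  class_means <- do.call(rbind, lapply(classes, function(cl)
    colMeans(scores[labels == cl, , drop = FALSE])))
  rownames(class_means) <- classes
  pred <- classes[apply(scores, 1L, function(s)
    which.min(colSums((t(class_means) - s)^2)))]
  model <- structure(
    list(class_labels = classes, discriminant_axes = axes,
         class_means = class_means, mean_vector = grand,
         eigenvalues = eb$values[seq_len(k)],
         scores = scores, labels = labels,
         accuracy = mean(pred == labels)),
    class = "shape_lda")
  model
}

rcond_sym <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

#' @export
print.shape_lda <- function(x, ...) {
  cat("Shape LDA:", length(x$class_labels), "classes (",
      paste(x$class_labels, collapse = ", "), ") ->",
      ncol(x$discriminant_axes), "discriminant axes\n")
  cat("  training accuracy (nearest class mean):",
      sprintf("%.3f", x$accuracy), "\n")
  invisible(x)
}

#' Project shape vectors onto the discriminant axes
#'
#' @param model A `shape_lda`.
#' @param v Shape vector or matrix of row vectors.
#' @return Score matrix (columns = discriminant axes).
#' @export
lda_scores <- function(model, v) {
  stopifnot(inherits(model, "shape_lda"))
  v <- if (is.null(dim(v))) matrix(v, nrow = 1L) else as.matrix(v)
  if (ncol(v) != length(model$mean_vector))
    stop("dimension error: vector length does not match model", call. = FALSE)
  sweep(v, 2L, model$mean_vector) %*% model$discriminant_axes
}

#' Classify shape vectors with a fitted LDA
#'
#' @param object A `shape_lda`.
#' @param newdata Shape vector or matrix of row vectors.
#' @param ... Unused.
#' @return Character vector of predicted class labels (nearest class mean
#'   in discriminant space).
#' @export
predict.shape_lda <- function(object, newdata, ...) {
  s <- lda_scores(object, newdata)
  object$class_labels[apply(s, 1L, function(si)
    which.min(colSums((t(object$class_means) - si)^2)))]
}

#' Serialize ordination models to JSON
#'
#' @param model A `shape_pca` or `shape_lda`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_model_json <- function(model, path) {
  doc <- if (inherits(model, "shape_pca")) {
    list(type = "shape_pca", mean_vector = unname(model$mean_vector),
         components = unname(model$components),
         explained_variance = model$explained_variance,
         total_variance = model$total_variance)
  } else if (inherits(model, "shape_lda")) {
    list(type = "shape_lda", class_labels = model$class_labels,
         discriminant_axes = unname(model$discriminant_axes),
         class_means = unname(model$class_means),
         mean_vector = unname(model$mean_vector))
  } else stop("unsupported model type", call. = FALSE)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
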