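#' Landmark scheme
#'
#' A landmark scheme names the ordered set of homologous 2-D points digitized
#' on every leaf of a dataset, and optionally the pair of landmarks defining
#' the petiolar-junction to leaf-tip midline used for reflection completion.
#'
#' @param name Scheme name.
#' @param landmark_names Character vector of landmark names, in digitization
#'   order.
#' @param axis_indices Optional integer pair: indices (1-based) of the two
#'   landmarks spanning the petiolar-junction to leaf-tip axis, or `NULL`.
#' @return An object of class `landmark_scheme` with fields `name`,
#'   `n_landmarks`, `landmark_names` and `axis_indices`.
#' @seealso [builtin_scheme()] for the built-in grapevine, maracuya and
#'   shared schemes.
#' @export
landmark_scheme <- function(name, landmark_names, axis_indices = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  landmark_names <- as.character(landmark_names)
  n <- length(landmark_names)
  if (n < 1L)
    stop("a landmark scheme needs at least one landmark", call. = FALSE)
  if (anyDuplicated(landmark_names))
    stop("landmark names must be unique", call. = FALSE)
  if (!is.null(axis_indices)) {
    axis_indices <- as.integer(axis_indices)
    if (length(axis_indices) != 2L || anyNA(axis_indices) ||
        any(axis_indices < 1L | axis_indices > n) ||
        axis_indices[1L] == axis_indices[2L])
      stop("axis_indices must be two distinct valid landmark indices",
           call. = FALSE)
  }
  structure(
    list(name = name, n_landmarks = n, landmark_names = landmark_names,
         axis_indices = axis_indices),
    class = "landmark_scheme")
}

#' Built-in landmark schemes
#'
#' Three schemes are built in: `"grapevine"` (15 landmarks digitized on one
#' half of the leaf, axis from petiolar junction to leaf tip), `"maracuya"`
#' (21 landmarks covering both sides of the leaf) and `"shared"` (the six
#' landmarks present in both: base of the petiolar junction, proximal lobe
#' tip, proximal sinus, distal lobe tip, distal lobe sinus and leaf tip).
#'
#' The grapevine and maracuya schemes use positional landmark names
#' (`lm01`, `lm02`, ...) with the first landmark the petiolar-junction base
#' and the last the leaf tip; the published figures show the points but the
#' text does not enumerate them.
#'
#' @param name One of `"grapevine"`, `"maracuya"`, `"shared"`.
#' @return A [landmark_scheme()].
#' @export
builtin_scheme <- function(name = c("grapevine", "maracuya", "shared")) {
  name <- match.arg(name)
  switch(name,
    grapevine = landmark_scheme(
      "grapevine", sprintf("lm%02d", 1:15), axis_indices = c(1L, 15L)),
    maracuya = landmark_scheme(
      "maracuya", sprintf("lm%02d", 1:21), axis_indices = c(1L, 21L)),
    shared = landmark_scheme(
      "shared",
      c("petiolar_junction_base", "proximal_lobe_tip", "proximal_sinus",
        "distal_lobe_tip", "distal_lobe_sinus", "leaf_tip"),
      axis_indices = c(1L, 6L)))
}

#' @export
print.landmark_scheme <- function(x, ...) {
  cat("Landmark scheme '", x$name, "': ", x$n_landmarks, " landmarks\n",
      sep = "")
  if (!is.null(x$axis_indices))
    cat("  midline axis: landmarks", x$axis_indices[1L], "->",
        x$axis_indices[2L], "\n")
  invisible(x)
}

coordinate_columns <- function(scheme) {
  as.vector(rbind(paste0("x", seq_len(scheme$n_landmarks)),
                  paste0("y", seq_len(scheme$n_landmarks))))
}
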