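#' Write a Mapper graph to GraphML
#'
#' Vertex attributes carried: `interval`, `size`, `mean_lens`,
#' `composition` (JSON string) and `mean_shape` (flattened
#' space-separated string); edges carry the shared-member count as
#' `weight`.
#'
#' @param graph A `mapper_graph`.
#' @param path Output `.graphml` path.
#' @return Invisibly, `path`.
#' @export
write_mapper_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' Write a Mapper graph to JSON
#'
#' A single document with vertices (members, annotations), edges, noise
#' and the full parameter provenance.
#'
#' @param graph A `mapper_graph`.
#' @param path Output `.json` path.
#' @return Invisibly, `path`.
#' @export
write_mapper_json <- function(graph, path) {
  stopifnot(inherits(graph, "mapper_graph"))
  doc <- list(
    params = graph$params[setdiff(names(graph$params), "cover")],
    cover = if (!is.null(graph$params$cover))
      unname(apply(graph$params$cover, 1L, as.list)) else NULL,
    vertices = lapply(graph$vertices, function(v) {
      list(vertex_id = v$vertex_id, interval_index = v$interval_index,
           members = as.list(v$members), size = v$size,
           mean_lens = v$mean_lens,
           composition = as.list(v$composition %||% list()),
           mean_shape = if (is.null(v$mean_shape)) NULL else
             unname(as.vector(t(v$mean_shape))))
    }),
    edges = if (nrow(graph$edges)) graph$edges else NULL,
    noise = graph$noise)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write the leaf-to-vertex membership table
#'
#' One row per (leaf, vertex) membership; a leaf in two overlapping
#' intervals appears once per vertex containing it.
#'
#' @param graph A `mapper_graph`.
#' @param path Output `.csv` path.
#' @return Invisibly, `path`.
#' @export
write_mapper_membership <- function(graph, path) {
  stopifnot(inherits(graph, "mapper_graph"))
  rows <- do.call(rbind, lapply(graph$vertices, function(v)
    data.frame(leaf_id = v$members, vertex_id = v$vertex_id,
               interval_index = v$interval_index,
               stringsAsFactors = FALSE)))
  if (is.null(rows))
    rows <- data.frame(leaf_id = character(), vertex_id = character(),
                       interval_index = integer())
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# deterministic layout: x = vertex mean lens, y = clusters of an interval
# stacked symmetrically about zero
mapper_layout <- function(graph) {
  iv <- vapply(graph$vertices, function(v) as.integer(v$interval_index),
               integer(1L))
  ml <- vapply(graph$vertices, function(v) as.numeric(v$mean_lens),
               numeric(1L))
  y <- numeric(length(iv))
  for (k in unique(iv)) {
    idx <- which(iv == k)
    y[idx] <- seq_along(idx) - (length(idx) + 1) / 2
  }
  cbind(x = ml, y = y)
}

draw_pie <- function(cx, cy, r, shares, cols, n_arc = 48L) {
  shares <- shares / sum(shares)
  a0 <- pi / 2
  for (s in seq_along(shares)) {
    a1 <- a0 - 2 * pi * shares[s]
    th <- seq(a0, a1, length.out = max(3L, ceiling(n_arc * shares[s])))
    graphics::polygon(c(cx, cx + r * cos(th)), c(cy, cy + r * sin(th)),
                      col = cols[s], border = "grey30", lwd = 0.5)
    a0 <- a1
  }
}

#' Plot a Mapper graph
#'
#' Vertices are drawn at x = mean lens value (clusters of one interval
#' stacked vertically), sized by member count, and rendered either as pie
#' charts of their group-label composition or colored by mean lens value.
#' Group colors follow a fixed order: labels sorted lexicographically.
#'
#' @param x A `mapper_graph`.
#' @param vertex_style `"pie"` (composition) or `"lens"` (mean lens).
#' @param vertex_scale Multiplier for vertex radii.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the layout matrix.
#' @export
plot.mapper_graph <- function(x, vertex_style = c("pie", "lens"),
                              vertex_scale = 1, ...) {
  vertex_style <- match.arg(vertex_style)
  if (!length(x$vertices)) stop("empty Mapper graph", call. = FALSE)
  lay <- mapper_layout(x)
  ids <- vapply(x$vertices, `[[`, character(1L), "vertex_id")
  sizes <- vapply(x$vertices, `[[`, integer(1L), "size")
  xr <- range(lay[, 1L]); yr <- range(lay[, 2L])
  pad <- 0.08 * max(diff(xr), 1e-9)
  graphics::plot(NA, xlim = xr + c(-pad, pad),
                 ylim = yr + c(-0.8, 0.8), xlab = paste0("mean lens (",
                 x$params$lens, ")"), ylab = "", yaxt = "n", ...)
  if (nrow(x$edges)) {
    i1 <- match(x$edges$from, ids); i2 <- match(x$edges$to, ids)
    graphics::segments(lay[i1, 1L], lay[i1, 2L], lay[i2, 1L], lay[i2, 2L],
                       col = "grey60")
  }
  r <- vertex_scale * (0.2 + 0.15 * sqrt(sizes / max(sizes))) *
    max(diff(xr), 1e-9) / 10
  if (vertex_style == "pie") {
    all_labels <- sort(unique(unlist(lapply(x$vertices, function(v)
      names(v$composition)))))
    pal <- grDevices::hcl.colors(max(length(all_labels), 2L), "Dark 3")
    for (i in seq_along(x$vertices)) {
      comp <- x$vertices[[i]]$composition
      cols <- pal[match(names(comp), all_labels)]
      draw_pie(lay[i, 1L], lay[i, 2L], r[i], as.numeric(comp), cols)
    }
    graphics::legend("topleft", legend = all_labels, fill = pal,
                     bty = "n", cex = 0.7)
  } else {
    ml <- vapply(x$vertices, function(v) as.numeric(v$mean_lens), numeric(1L))
    pal <- grDevices::hcl.colors(101L, "Viridis")
    rng <- range(ml)
    idx <- if (diff(rng) == 0) rep(51L, length(ml)) else
      1L + round(100 * (ml - rng[1L]) / diff(rng))
    graphics::symbols(lay[, 1L], lay[, 2L], circles = r, inches = FALSE,
                      add = TRUE, bg = pal[idx], fg = "grey30")
  }
  invisible(lay)
}

#' Plot the subway map of a Mapper graph
#'
#' Renders the primary structure with each vertex replaced by its mean
#' leaf shape — a tangible picture of how leaf shape changes along the
#' developmental spine and its branches.
#'
#' @param graph A `mapper_graph` whose vertices carry `mean_shape` (as
#'   produced by [leaf_mapper()]); typically first simplified with
#'   [extract_primary_structure()].
#' @param shape_scale Multiplier for the drawn shape glyphs.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the layout matrix.
#' @export
plot_subway <- function(graph, shape_scale = 1, ...) {
  stopifnot(inherits(graph, "mapper_graph"))
  if (!length(graph$vertices)) stop("empty Mapper graph", call. = FALSE)
  lay <- mapper_layout(graph)
  ids <- vapply(graph$vertices, `[[`, character(1L), "vertex_id")
  xr <- range(lay[, 1L]); yr <- range(lay[, 2L])
  pad <- 0.1 * max(diff(xr), 1e-9)
  graphics::plot(NA, xlim = xr + c(-pad, pad), ylim = yr + c(-0.8, 0.8),
                 xlab = paste0("mean lens (", graph$params$lens, ")"),
                 ylab = "", yaxt = "n", ...)
  if (nrow(graph$edges)) {
    i1 <- match(graph$edges$from, ids); i2 <- match(graph$edges$to, ids)
    graphics::segments(lay[i1, 1L], lay[i1, 2L], lay[i2, 1L], lay[i2, 2L],
                       col = "grey50", lwd = 2)
  }
  glyph <- shape_scale * max(diff(xr), 1e-9) / 18
  for (i in seq_along(graph$vertices)) {
    ms <- graph$vertices[[i]]$mean_shape
    if (is.null(ms)) next
    ms <- normalize_shape(ms) * glyph * 3
    graphics::polygon(lay[i, 1L] + ms[, 1L], lay[i, 2L] + ms[, 2L],
                      col = "white", border = "black", lwd = 0.8)
  }
  invisible(lay)
}
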