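#' Read a landmark table
#'
#' Reads a delimited text table of per-leaf landmarks and metadata into a
#' [leaf_dataset()]. The delimiter is taken from the file extension
#' (`.tsv`/`.txt` = tab, otherwise comma). The column map names the metadata
#' columns and, optionally, the coordinate columns; by default coordinates
#' are expected in columns `x1, y1, ..., xn, yn`.
#'
#' Rows with missing coordinates are dropped with a warning naming their row
#' numbers. A coordinate-column count that does not match the scheme is a
#' schema error; a non-numeric coordinate is a parse error reporting the row;
#' duplicate leaf ids are an integrity error.
#'
#' @param source Path to a delimited text file, or a connection.
#' @param scheme A [landmark_scheme()] (or the name of a built-in scheme).
#' @param column_map Named list with entries `leaf_id`, `group_label`,
#'   `vine_id`, `node_index`, and optionally `coords` (character vector of
#'   the 2n coordinate column names in landmark order) and `relative_node`.
#'   `dryad_column_map()` gives the preset for the published data layout.
#' @param sep Field separator; `NULL` (default) autodetects from the
#'   file extension.
#' @param provenance Provenance string stored on the dataset; defaults to
#'   the source path.
#' @return A validated [leaf_dataset()].
#' @export
read_landmark_table <- function(source, scheme,
                                column_map = default_column_map(),
                                sep = NULL, provenance = NULL) {
  if (is.character(scheme)) scheme <- builtin_scheme(scheme)
  if (is.null(sep)) {
    sep <- if (is.character(source) &&
               grepl("\\.(tsv|txt)$", source, ignore.case = TRUE)) "\t" else ","
  }
  if (is.null(provenance))
    provenance <- if (is.character(source)) source else "connection"
  tab <- utils::read.table(source, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  for (key in c("leaf_id", "group_label", "vine_id", "node_index")) {
    colname <- column_map[[key]]
    if (is.null(colname) || !colname %in% names(tab))
      stop("column_map entry '", key, "' (", colname %||% "missing",
           ") not found in table", call. = FALSE)
  }
  coord_cols <- column_map$coords %||% coordinate_columns(scheme)
  absent <- setdiff(coord_cols, names(tab))
  if (length(absent))
    stop("schema error: scheme '", scheme$name, "' expects ",
         2L * scheme$n_landmarks, " coordinate columns; missing: ",
         paste(absent, collapse = ", "), call. = FALSE)
  if (length(coord_cols) != 2L * scheme$n_landmarks)
    stop("schema error: ", length(coord_cols),
         " coordinate columns mapped but scheme '", scheme$name,
         "' requires ", 2L * scheme$n_landmarks, call. = FALSE)

  if (nrow(tab) == 0L) {
    return(leaf_dataset(scheme,
      data.frame(leaf_id = character(), group_label = character(),
                 vine_id = character(), node_index = integer()),
      matrix(numeric(), 0L, 2L * scheme$n_landmarks), provenance))
  }

  raw <- tab[, coord_cols, drop = FALSE]
  missing_row <- apply(raw, 1L, function(r) any(is.na(r) | r == ""))
  if (any(missing_row)) {
    warning("dropping ", sum(missing_row),
            " row(s) with missing coordinates (rows ",
            paste(which(missing_row), collapse = ", "), ")", call. = FALSE)
    tab <- tab[!missing_row, , drop = FALSE]
    raw <- raw[!missing_row, , drop = FALSE]
  }
  suppressWarnings(coords <- vapply(raw, as.numeric, numeric(nrow(raw))))
  coords <- matrix(coords, nrow = nrow(raw))
  if (anyNA(coords)) {
    bad <- which(apply(coords, 1L, anyNA))
    stop("parse error: non-numeric coordinate in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  node_index <- suppressWarnings(as.integer(tab[[column_map$node_index]]))
  if (anyNA(node_index))
    stop("parse error: non-integer node_index", call. = FALSE)
  meta <- data.frame(
    leaf_id = tab[[column_map$leaf_id]],
    group_label = tab[[column_map$group_label]],
    vine_id = tab[[column_map$vine_id]],
    node_index = node_index,
    stringsAsFactors = FALSE)
  if (!is.null(column_map$relative_node) &&
      column_map$relative_node %in% names(tab))
    meta$relative_node <- suppressWarnings(
      as.numeric(tab[[column_map$relative_node]]))
  leaf_dataset(scheme, meta, coords, provenance)
}

#' Default and preset column maps
#'
#' `default_column_map()` expects the package's own layout (`leaf_id`,
#' `group_label`, `vine_id`, `node_index`, coordinates `x1, y1, ...`).
#' `dryad_column_map()` maps the deposited data layout, whose metadata
#' columns are named `leaf`, `species`, `vine` and `node`.
#'
#' @param n_landmarks For `dryad_column_map()`, the landmark count used to
#'   name the coordinate columns.
#' @return A named list usable as `column_map` in [read_landmark_table()].
#' @export
default_column_map <- function() {
  list(leaf_id = "leaf_id", group_label = "group_label", vine_id = "vine_id",
       node_index = "node_index", relative_node = "relative_node")
}

#' @rdname default_column_map
#' @export
dryad_column_map <- function(n_landmarks = 15L) {
  list(leaf_id = "leaf", group_label = "species", vine_id = "vine",
       node_index = "node",
       coords = as.vector(rbind(paste0("x", seq_len(n_landmarks)),
                                paste0("y", seq_len(n_landmarks)))))
}

#' Write a landmark table
#'
#' Writes a [leaf_dataset()] back to delimited text in the standard layout,
#' so that `read_landmark_table()` round-trips it exactly (coordinates at
#' full precision, metadata verbatim).
#'
#' @param x A `leaf_dataset`.
#' @param path Output path; `.tsv` writes tab-separated, otherwise CSV.
#' @return Invisibly, `path`.
#' @export
write_landmark_table <- function(x, path) {
  stopifnot(inherits(x, "leaf_dataset"))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- as.data.frame(x)
  # full-precision coordinates so read -> write -> read is the identity
  for (j in which(vapply(df, is.double, logical(1L)))) {
    keep_na <- is.na(df[[j]])
    df[[j]] <- sprintf("%.17g", df[[j]])
    df[[j]][keep_na] <- NA
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Serialize a dataset to and from JSON
#'
#' A single JSON document carrying the scheme and the leaves; used for
#' small fixtures and provenance capture.
#'
#' @param x A `leaf_dataset`.
#' @param path JSON file path.
#' @return `dataset_to_json` invisibly returns `path`; `dataset_from_json`
#'   returns a `leaf_dataset`.
#' @export
dataset_to_json <- function(x, path) {
  stopifnot(inherits(x, "leaf_dataset"))
  doc <- list(
    scheme = list(name = x$scheme$name,
                  landmark_names = x$scheme$landmark_names,
                  axis_indices = x$scheme$axis_indices),
    provenance = x$provenance,
    leaves = lapply(seq_len(n_leaves(x)), function(i) {
      list(leaf_id = x$meta$leaf_id[i], group_label = x$meta$group_label[i],
           vine_id = x$meta$vine_id[i], node_index = x$meta$node_index[i],
           relative_node = if (is.na(x$meta$relative_node[i])) NULL else
             x$meta$relative_node[i],
           coords = unname(x$coords[i, ]))
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname dataset_to_json
#' @export
dataset_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  scheme <- landmark_scheme(doc$scheme$name,
                            unlist(doc$scheme$landmark_names),
                            if (length(doc$scheme$axis_indices))
                              unlist(doc$scheme$axis_indices) else NULL)
  leaves <- doc$leaves
  meta <- data.frame(
    leaf_id = vapply(leaves, function(l) l$leaf_id, character(1L)),
    group_label = vapply(leaves, function(l) l$group_label, character(1L)),
    vine_id = vapply(leaves, function(l) l$vine_id, character(1L)),
    node_index = vapply(leaves, function(l) as.integer(l$node_index),
                        integer(1L)),
    relative_node = vapply(leaves, function(l)
      if (is.null(l$relative_node)) NA_real_ else as.numeric(l$relative_node),
      numeric(1L)),
    stringsAsFactors = FALSE)
  coords <- do.call(rbind, lapply(leaves, function(l)
    as.numeric(unlist(l$coords))))
  if (is.null(coords)) coords <- matrix(numeric(), 0L, 2L * scheme$n_landmarks)
  leaf_dataset(scheme, meta, coords, doc$provenance %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
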