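#' Analysis configuration
#'
#' Builds (and validates) the configuration driving
#' [run_leaf_analysis()]. A configuration can also be read from YAML with
#' [read_analysis_config()]; every Mapper run is fully parameterized — no
#' hidden defaults reach the outputs.
#'
#' @param datasets Named list, one entry per genus/dataset. Each entry is
#'   either `list(synthetic = list(...))` with [synth_config()] arguments,
#'   or `list(path = "...", scheme = "grapevine", column_map = "default")`
#'   (`column_map` one of `"default"`, `"dryad"`).
#' @param shared_landmarks Named list (same names): integer landmark
#'   selection mapping each dataset onto the common scheme for the joint
#'   morphospace.
#' @param reflect Named logical list: complete half-digitized leaves by
#'   midline reflection after subsetting (grapevine-style data).
#' @param split_threshold Relative-node threshold for the shoot-base /
#'   growing-tip split.
#' @param mapper List of Mapper parameters: `n_intervals`, `overlap`,
#'   `eps`, `min_samples`, `align`.
#' @param min_vertex_size Vertex-size threshold for
#'   [extract_primary_structure()].
#' @param seed Integer master seed.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(datasets, shared_landmarks = NULL,
                            reflect = NULL, split_threshold = 0.5,
                            mapper = list(), min_vertex_size = 2L,
                            seed = 1L) {
  stopifnot(is.list(datasets), length(datasets) >= 1L,
            !is.null(names(datasets)), all(nzchar(names(datasets))))
  mapper_defaults <- list(n_intervals = 12L, overlap = 0.35, eps = 0.05,
                          min_samples = 5L, align = FALSE)
  mapper <- utils::modifyList(mapper_defaults, mapper)
  if (!(split_threshold > 0 && split_threshold < 1))
    stop("split_threshold must lie strictly between 0 and 1", call. = FALSE)
  structure(
    list(datasets = datasets, shared_landmarks = shared_landmarks,
         reflect = reflect, split_threshold = split_threshold,
         mapper = mapper, min_vertex_size = as.integer(min_vertex_size),
         seed = as.integer(seed)),
    class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file with the fields of [analysis_config()].
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  analysis_config(
    datasets = y$datasets,
    shared_landmarks = y$shared_landmarks,
    reflect = y$reflect,
    split_threshold = y$split_threshold %||% 0.5,
    mapper = y$mapper %||% list(),
    min_vertex_size = y$min_vertex_size %||% 2L,
    seed = y$seed %||% 1L)
}

#' Demonstration two-genus synthetic configuration
#'
#' The ready-made configuration used by the examples and the worked
#' analyses: two synthetic "genera" on the 15-landmark scheme, sharing the
#' core heteroblastic and ontogenetic trajectory, distinguished by
#' genus-level offset fields; the second genus carries one divergent
#' species (its morphotype-A/B analogue) that branches off the spine in
#' the mid-series band and rejoins.
#'
#' @param seed Master seed; the two generators use `seed` and
#'   `seed + 1000`.
#' @param divergent Include the divergent species in the second genus.
#' @return An `analysis_config`.
#' @export
demo_two_genus_config <- function(seed = 1L, divergent = TRUE) {
  analysis_config(
    datasets = list(
      genusA = list(synthetic = list(seed = seed, genus_offset_sd = 0.12)),
      genusB = list(synthetic = c(list(seed = seed + 1000L,
                                       genus_offset_sd = 0.12),
                                  if (divergent)
                                    list(divergent_species = "sp04")))),
    shared_landmarks = list(genusA = c(1L, 3L, 5L, 8L, 11L, 13L),
                            genusB = c(1L, 3L, 5L, 8L, 11L, 13L)),
    reflect = list(genusA = FALSE, genusB = FALSE),
    seed = seed)
}

load_config_dataset <- function(entry, name) {
  if (!is.null(entry$synthetic)) {
    cfg <- do.call(synth_config, entry$synthetic)
    ds <- synth_leaf_series(cfg)
    ds$provenance <- sprintf("%s: %s", name, ds$provenance)
    ds
  } else if (!is.null(entry$path)) {
    cmap <- entry$column_map %||% "default"
    scheme <- builtin_scheme(entry$scheme %||% "grapevine")
    cmap <- switch(cmap,
                   default = default_column_map(),
                   dryad = dryad_column_map(scheme$n_landmarks),
                   stop("unknown column_map preset: ", cmap, call. = FALSE))
    read_landmark_table(entry$path, scheme, cmap)
  } else {
    stop("dataset entry '", name, "' needs either $synthetic or $path",
         call. = FALSE)
  }
}

#' Run the full leaf-shape analysis
#'
#' Orchestrates the whole pipeline for each configured dataset: ingest (or
#' generate), relative-node assignment, a PC1-lens Mapper, a
#' heteroblasty-lens Mapper, the shoot-base/growing-tip split with
#' per-part heteroblasty-lens Mappers (covers rebuilt over each part's own
#' lens range), graph diagnostics and primary-structure ("subway")
#' extraction. When at least two datasets are configured, a joint
#' morphospace is added: shared-landmark subsetting, optional reflection
#' completion, GPA, joint PCA, and an LDA of the four genus-by-position
#' groups (ontogenetic/heteroblastic series labels from the per-vine-mean
#' rule are emitted alongside). Deterministic given the configuration.
#'
#' @param config An [analysis_config()] (or path to its YAML).
#' @return An object of class `leaf_analysis`: per-dataset results
#'   (`datasets`, `mappers`, `diagnostics`, `subway`), joint-stage results
#'   (`gpa`, `pca`, `lda`, `scores`) and `provenance`.
#' @export
run_leaf_analysis <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "analysis_config"))
  mp <- config$mapper
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage ", what, "] ", conditionMessage(e), call. = FALSE))
  }

  datasets <- mappers <- diagnostics <- subway <- list()
  for (name in names(config$datasets)) {
    ds <- stage(paste0("ingest:", name),
                load_config_dataset(config$datasets[[name]], name))
    ds <- stage(paste0("relative_node:", name), assign_relative_node(ds))
    datasets[[name]] <- ds

    run_mapper <- function(d, lens)
      leaf_mapper(d, lens = lens, n_intervals = mp$n_intervals,
                  overlap = mp$overlap, eps = mp$eps,
                  min_samples = mp$min_samples, align = mp$align)
    mappers[[name]] <- stage(paste0("mapper:", name), list(
      pc1 = run_mapper(ds, "pc1"),
      heteroblasty = run_mapper(ds, "heteroblasty")))
    halves <- stage(paste0("split:", name),
                    split_by_position(ds, config$split_threshold))
    for (part in c("base", "tip")) {
      if (n_leaves(halves[[part]]) > 0L)
        mappers[[name]][[part]] <- stage(
          paste0("mapper:", name, ":", part),
          run_mapper(halves[[part]], "heteroblasty"))
    }
    diagnostics[[name]] <- lapply(mappers[[name]], graph_diagnostics)
    subway[[name]] <- stage(paste0("subway:", name),
      extract_primary_structure(mappers[[name]]$heteroblasty,
                                config$min_vertex_size))
  }

  joint <- NULL
  if (length(datasets) >= 2L) {
    joint <- stage("joint_morphospace",
                   joint_morphospace(datasets, config))
  }
  structure(
    list(config = config, datasets = datasets, mappers = mappers,
         diagnostics = diagnostics, subway = subway,
         gpa = joint$gpa, pca = joint$pca, lda = joint$lda,
         scores = joint$scores,
         provenance = list(seed = config$seed,
                           config_hash = config_hash(config),
                           timestamp = NULL)),
    class = "leaf_analysis")
}

# shared-landmark joint morphospace of the first two datasets
joint_morphospace <- function(datasets, config) {
  pair <- names(datasets)[1:2]
  parts <- list()
  for (name in pair) {
    ds <- datasets[[name]]
    sel <- config$shared_landmarks[[name]] %||%
      seq_len(min(vapply(datasets[pair], function(d) d$scheme$n_landmarks,
                         integer(1L))))
    sub <- subset_shared_landmarks(ds, as.integer(sel),
                                   scheme_for_selection(length(sel)))
    if (isTRUE(config$reflect[[name]]))
      sub <- reflect_to_complete(sub)
    # prefix ids so the two genera coexist in one dataset
    sub$meta$leaf_id <- paste(name, sub$meta$leaf_id, sep = ":")
    sub$meta$vine_id <- paste(name, sub$meta$vine_id, sep = ":")
    sub$meta$group_label <- name
    parts[[name]] <- sub
  }
  schemes <- vapply(parts, function(p) p$scheme$n_landmarks, integer(1L))
  if (length(unique(schemes)) != 1L)
    stop("shared-landmark selections map the datasets to different sizes",
         call. = FALSE)
  combined <- leaf_dataset(
    parts[[1L]]$scheme,
    do.call(rbind, lapply(parts, `[[`, "meta")),
    do.call(rbind, lapply(parts, `[[`, "coords")),
    provenance = "joint shared-landmark morphospace")
  fit <- gpa(combined)
  aligned <- fit$aligned
  pca <- shape_pca(aligned)

  genus <- sub(":.*$", "", aligned$meta$leaf_id)
  position <- ifelse(aligned$meta$relative_node > config$split_threshold,
                     "base", "tip")
  series <- rep(NA_character_, n_leaves(aligned))
  sv <- split_by_vine_mean(aligned)
  series[match(sv$heteroblastic$meta$leaf_id, aligned$meta$leaf_id)] <-
    "heteroblastic"
  series[match(sv$ontogenetic$meta$leaf_id, aligned$meta$leaf_id)] <-
    "ontogenetic"
  group4 <- paste(genus, position, sep = "_")
  lda <- shape_lda(flatten_leaves(aligned), group4)
  pcs <- pca_scores(pca, flatten_leaves(aligned))
  lds <- lda_scores(lda, flatten_leaves(aligned))
  scores <- data.frame(
    leaf_id = aligned$meta$leaf_id, genus = genus, position = position,
    series = series, group = group4,
    relative_node = aligned$meta$relative_node,
    stringsAsFactors = FALSE)
  scores <- cbind(scores,
                  stats::setNames(as.data.frame(pcs[, 1:min(4L, ncol(pcs)),
                                                    drop = FALSE]),
                                  paste0("PC", 1:min(4L, ncol(pcs)))),
                  stats::setNames(as.data.frame(lds),
                                  colnames(lds)))
  rownames(scores) <- NULL
  list(gpa = fit, pca = pca, lda = lda, scores = scores)
}

scheme_for_selection <- function(k) {
  if (k == 6L) builtin_scheme("shared") else NULL
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}

#' @export
print.leaf_analysis <- function(x, ...) {
  cat("Leaf-shape analysis (seed ", x$config$seed, ", config ",
      substr(x$provenance$config_hash, 1L, 8L), ")\n", sep = "")
  for (name in names(x$datasets)) {
    d <- x$diagnostics[[name]]$heteroblasty
    cat("  ", name, ": ", n_leaves(x$datasets[[name]]), " leaves; ",
        "heteroblasty Mapper V=", d$n_vertices, " E=", d$n_edges,
        " b1=", d$cycle_rank,
        " spine monotonicity=", sprintf("%.2f", d$spine_monotonicity),
        "\n", sep = "")
  }
  if (!is.null(x$lda))
    cat("  joint LDA accuracy:", sprintf("%.3f", x$lda$accuracy), "\n")
  invisible(x)
}

#' Extract the primary structure of a Mapper graph
#'
#' The "subway map" simplification: keep vertices with at least
#' `min_vertex_size` members, restrict to the largest connected component
#' of the surviving subgraph, and carry all vertex annotations (mean
#' shapes, composition) along. Never adds vertices or edges. The published
#' figures describe this step only as highlighting the central spine and
#' branches; the size-threshold-plus-largest-component realization is this
#' package's concrete choice.
#'
#' @param graph A `mapper_graph`.
#' @param min_vertex_size Minimum member count for a vertex to survive.
#' @return The simplified `mapper_graph`.
#' @export
extract_primary_structure <- function(graph, min_vertex_size = 2L) {
  stopifnot(inherits(graph, "mapper_graph"), min_vertex_size >= 1L)
  keep <- vapply(graph$vertices, function(v) v$size >= min_vertex_size,
                 logical(1L))
  if (!any(keep))
    stop("no vertex has >= ", min_vertex_size, " members", call. = FALSE)
  vertices <- graph$vertices[keep]
  ids <- vapply(vertices, `[[`, character(1L), "vertex_id")
  edges <- graph$edges[graph$edges$from %in% ids & graph$edges$to %in% ids, ,
                       drop = FALSE]
  sub <- structure(list(vertices = vertices, edges = edges, noise = list(),
                        params = graph$params),
                   class = "mapper_graph")
  g <- as_igraph(sub)
  comp <- igraph::components(g)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1L) {
    # tie-break: component containing the lexicographically smallest id
    firsts <- vapply(big, function(b)
      min(igraph::V(g)$name[comp$membership == b]), character(1L))
    big <- big[order(firsts)][1L]
  }
  keep_ids <- igraph::V(g)$name[comp$membership == big]
  vertices <- vertices[ids %in% keep_ids]
  edges <- edges[edges$from %in% keep_ids & edges$to %in% keep_ids, ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(vertices = vertices, edges = edges, noise = list(),
                 params = c(graph$params,
                            list(min_vertex_size = min_vertex_size,
                                 primary_structure = TRUE))),
            class = "mapper_graph")
}

write_file_safely <- function(path, writer, manifest_env) {
  res <- tryCatch({ writer(path); TRUE },
                  error = function(e) {
                    warning("failed to write ", path, ": ",
                            conditionMessage(e), call. = FALSE)
                    FALSE
                  })
  if (res) assign(path, TRUE, envir = manifest_env)
  res
}

#' Export a results bundle to a directory
#'
#' Writes, for every Mapper graph, GraphML and JSON documents plus the
#' membership CSV; the PCA/LDA models as JSON; the score table and aligned
#' coordinates as CSV; all diagnostics as one JSON; static plots (PCA
#' scatter colored by group and by heteroblasty, Mapper graphs with pie
#' vertices, subway maps); and a provenance log. Returns a manifest of
#' every file with an MD5 checksum. Identical inputs produce identical
#' text outputs.
#'
#' @param bundle A `leaf_analysis`.
#' @param outdir Output directory (created if needed).
#' @param plots Write PNG plots (set `FALSE` on headless systems without
#'   a PNG device).
#' @return Invisibly, the manifest data frame (`file`, `md5`).
#' @export
export_bundle <- function(bundle, outdir, plots = TRUE) {
  stopifnot(inherits(bundle, "leaf_analysis"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  put <- function(rel, writer) {
    path <- file.path(outdir, rel)
    ok <- tryCatch({ writer(path); TRUE },
                   error = function(e) {
                     warning("failed to write ", rel, ": ",
                             conditionMessage(e), call. = FALSE)
                     FALSE
                   })
    if (ok) written <<- c(written, path)
  }

  for (name in names(bundle$mappers)) {
    for (kind in names(bundle$mappers[[name]])) {
      graph <- bundle$mappers[[name]][[kind]]
      stemname <- paste0("mapper_", name, "_", kind)
      put(paste0(stemname, ".graphml"),
          function(p) write_mapper_graphml(graph, p))
      put(paste0(stemname, ".json"),
          function(p) write_mapper_json(graph, p))
      put(paste0(stemname, "_membership.csv"),
          function(p) write_mapper_membership(graph, p))
    }
    put(paste0("subway_", name, ".json"),
        function(p) write_mapper_json(bundle$subway[[name]], p))
    put(paste0("subway_", name, ".graphml"),
        function(p) write_mapper_graphml(bundle$subway[[name]], p))
  }
  put("diagnostics.json", function(p)
    jsonlite::write_json(bundle$diagnostics, p, auto_unbox = TRUE,
                         digits = NA))
  if (!is.null(bundle$pca))
    put("pca_model.json", function(p) write_model_json(bundle$pca, p))
  if (!is.null(bundle$lda))
    put("lda_model.json", function(p) write_model_json(bundle$lda, p))
  if (!is.null(bundle$scores))
    put("scores.csv", function(p)
      utils::write.csv(bundle$scores, p, row.names = FALSE, quote = FALSE))
  if (!is.null(bundle$gpa))
    put("aligned_shared.csv", function(p)
      write_landmark_table(bundle$gpa$aligned, p))
  put("provenance.json", function(p)
    jsonlite::write_json(
      list(seed = bundle$config$seed,
           config_hash = bundle$provenance$config_hash,
           config = unclass(bundle$config),
           mapper_params = bundle$config$mapper),
      p, auto_unbox = TRUE, digits = NA, force = TRUE))

  if (plots && capabilities("png")) {
    for (name in names(bundle$mappers)) {
      put(paste0("mapper_", name, "_heteroblasty.png"), function(p) {
        grDevices::png(p, 900, 700)
        on.exit(grDevices::dev.off())
        plot(bundle$mappers[[name]]$heteroblasty, vertex_style = "pie",
             main = paste(name, "- heteroblasty lens"))
      })
      put(paste0("subway_", name, ".png"), function(p) {
        grDevices::png(p, 900, 700)
        on.exit(grDevices::dev.off())
        plot_subway(bundle$subway[[name]],
                    main = paste(name, "- primary structure"))
      })
    }
    if (!is.null(bundle$scores)) {
      put("pca_scatter.png", function(p) {
        grDevices::png(p, 1400, 700)
        on.exit(grDevices::dev.off())
        graphics::par(mfrow = c(1, 2))
        sc <- bundle$scores
        groups <- sort(unique(sc$group))
        pal <- grDevices::hcl.colors(max(length(groups), 2L), "Dark 3")
        graphics::plot(sc$PC1, sc$PC2, col = pal[match(sc$group, groups)],
                       pch = 19, cex = 0.6, xlab = "PC1", ylab = "PC2",
                       main = "shared morphospace by group")
        graphics::legend("topright", legend = groups, col = pal, pch = 19,
                         cex = 0.7, bty = "n")
        vir <- grDevices::hcl.colors(101L, "Viridis")
        graphics::plot(sc$PC1, sc$PC2,
                       col = vir[1L + round(100 * sc$relative_node)],
                       pch = 19, cex = 0.6, xlab = "PC1", ylab = "PC2",
                       main = "shared morphospace by heteroblasty")
      })
    }
  }
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
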