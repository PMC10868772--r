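#' Synthetic leaf-series configuration
#'
#' Parameters of the generative model behind [synth_leaf_series()]. The
#' generator emulates the layout of the real data — several species, each
#' with several vines carrying an ordered node series — with a shared
#' smooth heteroblastic shape trajectory, ontogenetic allometric expansion
#' near the growing tip, fixed per-species offset fields, optional
#' morphotype-style mid-series divergence that vanishes at both band edges,
#' and Gaussian landmark noise.
#'
#' @param n_species Number of species.
#' @param vines_per_species Vines per species.
#' @param nodes_per_vine Leaves (nodes) per vine; node 1 is the growing
#'   tip.
#' @param n_landmarks Landmarks per leaf (default 15, the grapevine
#'   scheme size).
#' @param heteroblasty_amplitude Strength of the shared heteroblastic
#'   deformation (lobe deepening and aspect change), scaled by relative
#'   node position r.
#' @param ontogeny_amplitude Strength of the ontogenetic allometric effect
#'   (tip leaves smaller and elongated), scaled by 1 - r.
#' @param species_effect_sd SD of each species' fixed landmark offset
#'   field, in shape units (centroid size of the template is 1).
#' @param genus_offset_sd SD of one additional offset field shared by all
#'   species of the dataset — a genus-level shape difference, used when two
#'   generated datasets stand in for two genera in a common morphospace.
#' @param divergent_species Character vector of species labels (e.g.
#'   `"sp01"`) whose mid-series trajectory diverges from the core program.
#' @param divergence_band Relative-node interval `[lo, hi]` in which the
#'   divergence acts.
#' @param divergence_amplitude Peak magnitude of the divergence
#'   displacement field (per-coordinate RMS, shape units).
#' @param noise_sd SD of the per-coordinate Gaussian landmark noise.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_species = 4L, vines_per_species = 5L,
                         nodes_per_vine = 30L, n_landmarks = 15L,
                         heteroblasty_amplitude = 1,
                         ontogeny_amplitude = 1.0,
                         species_effect_sd = 0.02,
                         genus_offset_sd = 0,
                         divergent_species = character(),
                         divergence_band = c(0.3, 0.7),
                         divergence_amplitude = 0.15,
                         noise_sd = 0.01,
                         seed = 1L) {
  cfg <- list(n_species = as.integer(n_species),
              vines_per_species = as.integer(vines_per_species),
              nodes_per_vine = as.integer(nodes_per_vine),
              n_landmarks = as.integer(n_landmarks),
              heteroblasty_amplitude = heteroblasty_amplitude,
              ontogeny_amplitude = ontogeny_amplitude,
              species_effect_sd = species_effect_sd,
              genus_offset_sd = genus_offset_sd,
              divergent_species = as.character(divergent_species),
              divergence_band = as.numeric(divergence_band),
              divergence_amplitude = divergence_amplitude,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_species >= 1L, vines_per_species >= 1L,
              nodes_per_vine >= 1L, n_landmarks >= 3L,
              heteroblasty_amplitude >= 0, ontogeny_amplitude >= 0,
              species_effect_sd >= 0, genus_offset_sd >= 0,
              divergence_amplitude >= 0,
              noise_sd >= 0, length(divergence_band) == 2L,
              divergence_band[1L] >= 0, divergence_band[2L] <= 1,
              divergence_band[1L] < divergence_band[2L])
  })
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic leaf-series config:", x$n_species, "species x",
      x$vines_per_species, "vines x", x$nodes_per_vine, "nodes,",
      x$n_landmarks, "landmarks, seed", x$seed, "\n")
  if (length(x$divergent_species))
    cat("  divergent:", paste(x$divergent_species, collapse = ", "),
        "in band [", x$divergence_band[1L], ",", x$divergence_band[2L],
        "], amplitude", x$divergence_amplitude, "\n")
  invisible(x)
}

#' Leaf template curve
#'
#' The fixed closed outline all synthetic leaves are sampled from: a
#' three-lobed, bilaterally symmetric polar curve with a petiolar notch,
#' tip pointing in +y. For parameter `t` in [0, 1) and angle
#' `theta = 2 * pi * t`,
#' `rho(theta) = 1 + 0.25 cos(3 theta) + 0.08 cos(6 theta)
#'  - 0.45 exp(-(theta - pi)^2 / 0.08)` and the point is
#' `rho * (sin theta, cos theta)`.
#'
#' @param t Numeric vector of curve parameters in [0, 1).
#' @return A `length(t)` x 2 matrix of (x, y) points.
#' @export
leaf_template_curve <- function(t) {
  theta <- 2 * pi * (t %% 1)
  rho <- 1 + 0.25 * cos(3 * theta) + 0.08 * cos(6 * theta) -
    0.45 * exp(-(theta - pi)^2 / 0.08)
  cbind(x = rho * sin(theta), y = rho * cos(theta))
}

#' Template leaf shape
#'
#' Samples the template curve at `n` evenly spaced parameters and
#' normalizes the result to centroid at the origin and centroid size 1.
#' Deterministic: the same `n` always yields the same shape, and shapes of
#' different `n` sample the same underlying curve.
#'
#' @param n_landmarks Number of landmarks (>= 3).
#' @return An `n_landmarks` x 2 landmark matrix.
#' @export
base_leaf_shape <- function(n_landmarks = 15L) {
  n_landmarks <- as.integer(n_landmarks)
  if (n_landmarks < 3L) stop("need at least 3 landmarks", call. = FALSE)
  normalize_shape(leaf_template_curve((seq_len(n_landmarks) - 1L) / n_landmarks))
}

# smooth bump on [lo, hi], vanishing at both edges, peak 1 at the center
divergence_bump <- function(r, lo, hi) {
  w <- numeric(length(r))
  inside <- r > lo & r < hi
  w[inside] <- sin(pi * (r[inside] - lo) / (hi - lo))^2
  w
}

#' Deform the template shape along the developmental trajectory
#'
#' Applies, in order: (i) the shared heteroblastic deformation — lobe
#' deepening and aspect change growing with relative node position r
#' (strong at the shoot base); (ii) the ontogenetic allometric effect —
#' overall contraction and elongation growing with 1 - r (strong at the
#' growing tip, where leaves are still expanding); (iii) a fixed
#' per-species offset field; (iv) for divergent species with r inside the
#' divergence band, an extra displacement scaled by a smooth bump that
#' vanishes at both band edges — the branch-and-rejoin ("reverse
#' hourglass") signal.
#'
#' @param shape n x 2 landmark matrix (the template).
#' @param r Relative node position in [0, 1] (0 = tip).
#' @param cfg A [synth_config()].
#' @param species_field Optional n x 2 fixed species offset field (shape
#'   units); `NULL` for none.
#' @param divergence_field Optional n x 2 unit-RMS divergence direction
#'   field; used only when `divergent = TRUE`.
#' @param divergent Is this leaf's species a divergent one?
#' @return The deformed n x 2 landmark matrix.
#' @export
deform_leaf <- function(shape, r, cfg, species_field = NULL,
                        divergence_field = NULL, divergent = FALSE) {
  stopifnot(r >= 0, r <= 1)
  p <- as.matrix(shape)
  theta <- atan2(p[, 1L], p[, 2L])
  # (i) heteroblastic: deepen lobes and widen with r
  h <- cfg$heteroblasty_amplitude * r
  radial <- 1 + 0.3 * h * cos(3 * theta)
  p <- p * radial
  p[, 1L] <- p[, 1L] * (1 + 0.25 * h)
  p[, 2L] <- p[, 2L] * (1 - 0.10 * h)
  # (ii) ontogenetic: tip leaves smaller and elongated
  o <- cfg$ontogeny_amplitude * (1 - r)
  p[, 2L] <- p[, 2L] * (1 + 0.45 * o)
  p[, 1L] <- p[, 1L] * (1 - 0.20 * o)
  p <- p / (1 + 1.5 * o)
  # (iii) fixed species offset
  if (!is.null(species_field)) p <- p + species_field
  # (iv) mid-series divergence, vanishing at the band edges
  if (divergent && !is.null(divergence_field)) {
    w <- divergence_bump(r, cfg$divergence_band[1L], cfg$divergence_band[2L])
    p <- p + cfg$divergence_amplitude * w * divergence_field
  }
  p
}

with_preserved_seed <- function(expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  expr
}

#' Generate a synthetic leaf-series dataset
#'
#' Produces `n_species * vines_per_species * nodes_per_vine` leaves with
#' full metadata (species label `spXX`, vine id, node index counted from
#' the tip). Draw order is fixed — first each species' offset and
#' divergence fields (in species order), then per-leaf noise in dataset
#' order — so adding vines does not perturb the species effects, and the
#' whole dataset is reproducible from `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @return A [leaf_dataset()]; `relative_node` is left unassigned so the
#'   full analysis path (including [assign_relative_node()]) can be
#'   exercised.
#' @export
synth_leaf_series <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_landmarks
  template <- base_leaf_shape(n)
  species <- sprintf("sp%02d", seq_len(cfg$n_species))
  unknown <- setdiff(cfg$divergent_species, species)
  if (length(unknown))
    stop("divergent_species not among generated labels: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  with_preserved_seed({
    set.seed(cfg$seed)
    # draw order: genus offset first, then per-species fields in species
    # order, then per-leaf noise in dataset order — adding vines never
    # perturbs the genus or species effects
    genus_offset <- matrix(stats::rnorm(2L * n, sd = cfg$genus_offset_sd),
                           n, 2L)
    fields <- lapply(species, function(s) {
      offset <- matrix(stats::rnorm(2L * n, sd = cfg$species_effect_sd),
                       n, 2L)
      dfield <- matrix(stats::rnorm(2L * n), n, 2L)
      dfield <- dfield / sqrt(mean(dfield^2))
      list(offset = offset, divergence = dfield)
    })
    names(fields) <- species

    total <- cfg$n_species * cfg$vines_per_species * cfg$nodes_per_vine
    meta <- data.frame(leaf_id = character(total),
                       group_label = character(total),
                       vine_id = character(total),
                       node_index = integer(total),
                       stringsAsFactors = FALSE)
    coords <- matrix(NA_real_, total, 2L * n)
    i <- 0L
    for (s in species) {
      for (v in seq_len(cfg$vines_per_species)) {
        vine_id <- sprintf("%s_v%02d", s, v)
        for (node in seq_len(cfg$nodes_per_vine)) {
          i <- i + 1L
          r <- if (cfg$nodes_per_vine == 1L) 0 else
            (node - 1) / (cfg$nodes_per_vine - 1)
          p <- deform_leaf(template, r, cfg,
                           species_field = fields[[s]]$offset + genus_offset,
                           divergence_field = fields[[s]]$divergence,
                           divergent = s %in% cfg$divergent_species)
          p <- p + matrix(stats::rnorm(2L * n, sd = cfg$noise_sd), n, 2L)
          meta$leaf_id[i] <- sprintf("%s_n%02d", vine_id, node)
          meta$group_label[i] <- s
          meta$vine_id[i] <- vine_id
          meta$node_index[i] <- node
          coords[i, ] <- as.vector(t(p))
        }
      }
    }
    scheme <- if (n == 15L) builtin_scheme("grapevine") else
      if (n == 21L) builtin_scheme("maracuya") else
        landmark_scheme(sprintf("synthetic_%d", n), sprintf("lm%02d", seq_len(n)))
    leaf_dataset(scheme, meta, coords,
                 provenance = sprintf("synthetic (seed %d)", cfg$seed))
  })
}

#' Write a synthetic dataset plus its configuration
#'
#' Writes the standard landmark CSV and the generating configuration as
#' YAML alongside it.
#'
#' @param cfg A [synth_config()].
#' @param csv_path Output CSV path; the YAML goes to the same path with
#'   extension `.yaml`.
#' @return Invisibly, the generated `leaf_dataset`.
#' @export
write_synth_dataset <- function(cfg, csv_path) {
  ds <- synth_leaf_series(cfg)
  write_landmark_table(ds, csv_path)
  yaml::write_yaml(unclass(cfg),
                   paste0(tools::file_path_sans_ext(csv_path), ".yaml"))
  invisible(ds)
}
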