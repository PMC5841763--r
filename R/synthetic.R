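## Synthetic data with known ground truth, emulating the sampling design of
## the congeneric-pair study system: 14 genera contributing 17 endemic /
## widespread pairs, about ten trees per species and five leaves per tree;
## lognormal traits with nested genus/species/tree/leaf variance; occurrence
## point clouds drawn from known polygons with planted outliers and
## within-cell duplicates; and tree-level environmental covariates with
## optional trait-environment couplings on the log scale.

DEFAULT_TRAIT_MEANS <- c(LA = 50, LT = 0.2, SLA = 120, LDMC = 0.35,
                         WSG = 0.55, N = 2, P = 0.12, NP = 16.7)

#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the study design the pipeline targets: 14 genera (three
#' contributing two congeneric pairs, eleven contributing one), ten trees
#' per species, five leaves per tree, lognormal traits whose log-scale
#' variance components put most variation between genera and species with
#' realistic tree-level CVs around 0.10.
#'
#' @param n_genera number of genera.
#' @param pairs_per_genus integer vector (length `n_genera`) of congeneric
#'   pairs contributed by each genus; each pair is one endemic plus one
#'   widespread species.
#' @param trees_per_species trees sampled per species.
#' @param leaves_per_tree leaves measured per tree (leaf-level traits).
#' @param variance_components named log-scale variances
#'   `c(genus, species, tree, leaf)`, all >= 0.
#' @param species_cv_targets optional data frame `(species, trait, cv)`
#'   giving target tree-level CVs; overrides the tree-level variance for
#'   those species x trait combinations via `sigma^2 = log(1 + cv^2)`.
#' @param env_effects optional data frame `(trait, climate, light, slope)`
#'   of log-scale linear coefficients applied by [generate_env_table()].
#' @param range_polygons optional named list (species -> two-column polygon
#'   matrix, planar km) of true ranges.
#' @param n_occurrences occurrence records per species.
#' @param outlier_fraction fraction of planted far outliers (of n).
#' @param duplicate_fraction fraction of planted within-cell duplicates.
#' @param trait_means named vector of trait means on the natural scale.
#' @param seed integer master seed; every stochastic draw in the generator
#'   descends from it through fixed per-stream offsets.
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genera = 14L,
                             pairs_per_genus = c(2L, 2L, 2L, rep(1L, 11L)),
                             trees_per_species = 10L,
                             leaves_per_tree = 5L,
                             variance_components = c(genus = 0.04, species = 0.02,
                                                     tree = 0.01, leaf = 0.005),
                             species_cv_targets = NULL,
                             env_effects = NULL,
                             range_polygons = NULL,
                             n_occurrences = 200L,
                             outlier_fraction = 0.02,
                             duplicate_fraction = 0.05,
                             trait_means = DEFAULT_TRAIT_MEANS,
                             seed = 1L) {
  n_genera <- check_count(n_genera, "n_genera")
  pairs_per_genus <- check_count(pairs_per_genus, "pairs_per_genus")
  if (length(pairs_per_genus) != n_genera)
    abort_validation("'pairs_per_genus' must have length n_genera")
  trees_per_species <- check_count(trees_per_species, "trees_per_species")
  leaves_per_tree <- check_count(leaves_per_tree, "leaves_per_tree")
  need <- c("genus", "species", "tree", "leaf")
  if (!all(need %in% names(variance_components)))
    abort_validation("'variance_components' must be named genus, species, tree, leaf")
  variance_components <- stats::setNames(
    check_nonneg(as.numeric(variance_components[need]), "variance_components"), need)
  if (!is.null(species_cv_targets)) {
    if (!all(c("species", "trait", "cv") %in% names(species_cv_targets)))
      abort_validation("'species_cv_targets' needs columns species, trait, cv")
    check_nonneg(species_cv_targets$cv, "species_cv_targets$cv")
  }
  if (!is.null(env_effects) && !"trait" %in% names(env_effects))
    abort_validation("'env_effects' needs a 'trait' column")
  outlier_fraction <- check_fraction(outlier_fraction, "outlier_fraction")
  duplicate_fraction <- check_fraction(duplicate_fraction, "duplicate_fraction")
  n_occurrences <- check_count(n_occurrences, "n_occurrences", min = 3L)
  if (!all(all_traits() %in% names(trait_means)))
    abort_validation("'trait_means' must cover all eight traits")
  structure(list(n_genera = n_genera, pairs_per_genus = pairs_per_genus,
                 trees_per_species = trees_per_species,
                 leaves_per_tree = leaves_per_tree,
                 variance_components = variance_components,
                 species_cv_targets = species_cv_targets,
                 env_effects = env_effects,
                 range_polygons = range_polygons,
                 n_occurrences = n_occurrences,
                 outlier_fraction = outlier_fraction,
                 duplicate_fraction = duplicate_fraction,
                 trait_means = trait_means,
                 seed = check_count(seed, "seed", min = 0L)),
            class = "synthetic_config")
}

## Species / pair / tree skeleton implied by a config.
design_table <- function(config) {
  rows <- list(); pair_no <- 0L
  for (g in seq_len(config$n_genera)) {
    genus <- sprintf("G%02d", g)
    for (p in seq_len(config$pairs_per_genus[g])) {
      pair_no <- pair_no + 1L
      pair <- sprintf("P%02d", pair_no)
      for (cls in c("endemic", "widespread")) {
        rows[[length(rows) + 1L]] <- data.frame(
          genus = genus, pair = pair, range_class = cls,
          species = sprintf("%s.%s.%s", genus, pair,
                            if (cls == "endemic") "end" else "wide"),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a nested trait dataset
#'
#' Trait values are drawn as
#' `mean * exp(genus + species + tree [+ leaf])` with independent normal
#' effects on the log scale, so values are strictly positive and the
#' within-species tree-level CV equals `sqrt(exp(sigma_tree^2) - 1)`
#' exactly in expectation.  Leaf-level traits (LA, LT, SLA, LDMC) receive
#' per-leaf noise; tree-level traits (WSG, N, P, N:P) have one value per
#' tree.  Deterministic for a fixed config seed.
#'
#' @param config a [synthetic_config()].
#' @return Tidy data frame of class `trait_dataset` with columns genus,
#'   species, pair, range_class, tree, leaf (`NA` for tree-level traits),
#'   trait, value.
#' @export
generate_trait_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  des <- design_table(config)
  nt <- config$trees_per_species
  trees <- des[rep(seq_len(nrow(des)), each = nt), , drop = FALSE]
  trees$tree <- sprintf("%s.t%02d", trees$species, rep(seq_len(nt), nrow(des)))
  rownames(trees) <- NULL
  vc <- config$variance_components
  targets <- config$species_cv_targets
  out <- with_seed(substream_seed(config$seed, 1L), {
    blocks <- lapply(all_traits(), function(tr) {
      g_eff <- stats::setNames(stats::rnorm(config$n_genera, 0, sqrt(vc[["genus"]])),
                               unique(des$genus))
      s_eff <- stats::setNames(stats::rnorm(nrow(des), 0, sqrt(vc[["species"]])),
                               des$species)
      sigma_tree <- rep(sqrt(vc[["tree"]]), nrow(trees))
      if (!is.null(targets)) {
        tt <- targets[targets$trait == tr, , drop = FALSE]
        hit <- match(trees$species, tt$species)
        sigma_tree[!is.na(hit)] <- sqrt(log(1 + tt$cv[hit[!is.na(hit)]]^2))
      }
      t_eff <- stats::rnorm(nrow(trees), 0, 1) * sigma_tree
      base <- config$trait_means[[tr]] *
        exp(g_eff[trees$genus] + s_eff[trees$species] + t_eff)
      if (tr %in% leaf_level_traits()) {
        nl <- config$leaves_per_tree
        leaf_noise <- stats::rnorm(nrow(trees) * nl, 0, sqrt(vc[["leaf"]]))
        d <- trees[rep(seq_len(nrow(trees)), each = nl), , drop = FALSE]
        d$leaf <- sprintf("l%02d", rep(seq_len(nl), nrow(trees)))
        d$trait <- tr
        d$value <- rep(base, each = nl) * exp(leaf_noise)
        d
      } else {
        d <- trees
        d$leaf <- NA_character_
        d$trait <- tr
        d$value <- base
        d
      }
    })
    do.call(rbind, blocks)
  })
  rownames(out) <- NULL
  class(out) <- c("trait_dataset", "data.frame")
  attr(out, "units") <- trait_units()
  out
}

polygon_diameter <- function(poly) {
  h <- poly[grDevices::chull(poly), , drop = FALSE]
  max(stats::dist(h))
}

#' Generate an occurrence point cloud with planted artefacts
#'
#' Draws `n` points uniformly inside a planar polygon; plants
#' `ceiling(outlier_fraction * n)` extra points far outside (evenly spaced
#' on a circle at least six polygon diameters from the centroid, enlarged
#' until the twice-mean-distance rule provably flags every one of them)
#' with suspicious locality metadata, and `ceiling(duplicate_fraction * n)`
#' extra points within the same 1-km grid cell (and < 1 km) of a randomly
#' chosen parent point.  Record ids are stable and ordered base < outliers
#' < duplicates, so grid deduplication retains the parents.
#'
#' @param polygon two-column matrix of polygon vertices (planar km),
#'   simple and with positive area.
#' @param n number of uniform base points (>= 3).
#' @param outlier_fraction,duplicate_fraction planted fractions in `[0, 1]`.
#' @param seed integer seed.
#' @param species species label for the records.
#' @return A planar `occurrence_set`; attribute `ground_truth` records the
#'   planted structure (base/outlier/duplicate ids, parents, true area).
#' @export
generate_occurrences <- function(polygon, n, outlier_fraction = 0,
                                 duplicate_fraction = 0, seed = 1,
                                 species = "species") {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L || polygon_area(polygon) <= 0)
    abort_validation("'polygon' is degenerate (needs >= 3 vertices and positive area)")
  n <- check_count(n, "n", min = 3L)
  outlier_fraction <- check_fraction(outlier_fraction, "outlier_fraction")
  duplicate_fraction <- check_fraction(duplicate_fraction, "duplicate_fraction")
  centroid <- colMeans(polygon[grDevices::chull(polygon), , drop = FALSE])
  diam <- polygon_diameter(polygon)
  with_seed(substream_seed(seed, 2L), {
    ## uniform points by rejection sampling in the bounding box
    xr <- range(polygon[, 1L]); yr <- range(polygon[, 2L])
    pts <- matrix(numeric(0), ncol = 2L)
    while (nrow(pts) < n) {
      m <- max(2L * (n - nrow(pts)), 16L)
      cand <- cbind(stats::runif(m, xr[1L], xr[2L]), stats::runif(m, yr[1L], yr[2L]))
      cand <- cand[point_in_polygon(cand, polygon), , drop = FALSE]
      pts <- rbind(pts, cand)
    }
    pts <- pts[seq_len(n), , drop = FALSE]
    flags <- rep("ok", n)
    n_out <- ceiling(outlier_fraction * n)
    if (n_out > 0L) {
      ## equal radius, evenly spaced angles; the radius is enlarged until
      ## every planted outlier's nearest neighbour provably exceeds twice
      ## the mean pairwise distance of the contaminated cloud (with margin),
      ## so the distance rule is guaranteed to see all of them
      theta <- stats::runif(1, 0, 2 * pi) + 2 * pi * (seq_len(n_out) - 1L) / n_out
      radius <- 6 * diam
      for (iter in 1:30) {
        outs <- cbind(centroid[1L] + radius * cos(theta),
                      centroid[2L] + radius * sin(theta))
        all_pts <- rbind(pts, outs)
        d <- as.matrix(stats::dist(all_pts))
        mpd <- mean(d[upper.tri(d)])
        diag(d) <- Inf
        nn_out <- apply(d[n + seq_len(n_out), , drop = FALSE], 1L, min)
        if (all(nn_out >= 2.1 * mpd)) break
        radius <- 2 * radius
      }
      pts <- rbind(pts, outs)
      flags <- c(flags, rep("suspicious", n_out))
    }
    n_dup <- ceiling(duplicate_fraction * n)
    parents <- integer(0)
    if (n_dup > 0L) {
      parents <- sample.int(n, n_dup, replace = n_dup > n)
      cell <- floor(pts[parents, , drop = FALSE])
      jit <- pts[parents, , drop = FALSE] +
        matrix(stats::runif(2L * n_dup, -0.005, 0.005), ncol = 2L)
      ## clamp into the parent's 1-km cell so the pair shares the cell
      jit[, 1L] <- pmin(pmax(jit[, 1L], cell[, 1L] + 1e-6), cell[, 1L] + 1 - 1e-6)
      jit[, 2L] <- pmin(pmax(jit[, 2L], cell[, 2L] + 1e-6), cell[, 2L] + 1 - 1e-6)
      pts <- rbind(pts, jit)
      flags <- c(flags, rep("ok", n_dup))
    }
    ids <- sprintf("rec%05d", seq_len(nrow(pts)))
    occ <- occurrence_set(species, pts, flags, mode = "planar", record_id = ids)
    attr(occ, "ground_truth") <- list(
      base_ids = ids[seq_len(n)],
      outlier_ids = if (n_out) ids[n + seq_len(n_out)] else character(),
      duplicate_ids = if (n_dup) ids[n + n_out + seq_len(n_dup)] else character(),
      parent_ids = if (n_dup) ids[parents] else character(),
      true_area_km2 = polygon_area(polygon))
    occ
  })
}

#' Generate tree-level environmental covariates
#'
#' One row per tree: slope (degrees, half-normal), crown-light index
#' (integer 0-5), and six climate variables driven by one dominant latent
#' factor with loading 0.912 on every standardized variable (so the first
#' ordination axis carries about 86% of the variance).  If `env_effects`
#' coefficients are supplied, trait values are regenerated with the linear
#' dependence `b_climate * factor + b_light * light + b_slope * slope`
#' added on the log scale, so residualization recovery is testable against
#' known ground truth.
#'
#' @param dataset a `trait_dataset`.
#' @param env_effects optional data frame `(trait, climate, light, slope)`.
#' @param seed integer seed.
#' @return List with `env` (data frame: tree, species, genus, slope, light,
#'   six `clim*` columns; attribute `climate_factor` holds the latent
#'   factor) and `traits` (the possibly regenerated `trait_dataset`).
#' @export
generate_env_table <- function(dataset, env_effects = NULL, seed = 1) {
  if (!nrow(dataset)) abort_validation("empty trait dataset")
  trees <- unique(dataset[, c("genus", "species", "tree")])
  rownames(trees) <- NULL
  n <- nrow(trees)
  clim_means <- c(26, 9, 75, 3500, 45, 900)
  clim_sds <- c(1.5, 1, 5, 400, 10, 150)
  loading <- 0.912
  out <- with_seed(substream_seed(seed, 3L), {
    slope <- abs(stats::rnorm(n, 0, 12))
    light <- sample(0:5, n, replace = TRUE)
    f <- stats::rnorm(n)
    clim <- vapply(seq_along(clim_means), function(j) {
      clim_means[j] + clim_sds[j] *
        (loading * f + sqrt(1 - loading^2) * stats::rnorm(n))
    }, numeric(n))
    colnames(clim) <- sprintf("clim%d", seq_along(clim_means))
    env <- data.frame(tree = trees$tree, species = trees$species,
                      genus = trees$genus, slope = slope, light = light,
                      stringsAsFactors = FALSE)
    env <- cbind(env, as.data.frame(clim))
    attr(env, "climate_factor") <- f
    env
  })
  traits <- dataset
  if (!is.null(env_effects)) {
    for (k in seq_len(nrow(env_effects))) {
      tr <- env_effects$trait[k]
      b_c <- env_effects$climate[k] %||% 0
      b_l <- env_effects$light[k] %||% 0
      b_s <- env_effects$slope[k] %||% 0
      if (all(c(b_c, b_l, b_s) == 0)) next
      i <- match(traits$tree, out$tree)
      sel <- traits$trait == tr
      mult <- exp(b_c * attr(out, "climate_factor")[i] +
                    b_l * out$light[i] + b_s * out$slope[i])
      traits$value[sel] <- traits$value[sel] * mult[sel]
    }
  }
  list(env = out, traits = traits)
}

#' Default true range polygons for a synthetic design
#'
#' Rectangles (convex, so alpha-shape area recovery is well-behaved) with
#' areas drawn log-uniformly: endemics between 10^2 and 10^4 km^2,
#' widespread species between 10^5 and 5x10^6 km^2, echoing the magnitudes
#' typical of endemic/widespread tropical tree pairs.
#'
#' @param meta data frame with columns `species` and `range_class`.
#' @param seed integer seed.
#' @return Named list of polygon matrices (planar km).
#' @export
default_range_polygons <- function(meta, seed = 1) {
  meta <- unique(meta[, c("species", "range_class")])
  with_seed(substream_seed(seed, 4L), {
    polys <- lapply(seq_len(nrow(meta)), function(i) {
      area <- if (meta$range_class[i] == "endemic")
        10^stats::runif(1, 2, 4) else 10^stats::runif(1, 5, log10(5e6))
      aspect <- stats::runif(1, 0.5, 2)
      w <- sqrt(area * aspect); h <- area / w
      rbind(c(0, 0), c(w, 0), c(w, h), c(0, h))
    })
    stats::setNames(polys, meta$species)
  })
}
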