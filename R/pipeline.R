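## End-to-end pipeline driver: simulate (or load) -> clean / range ->
## variability -> environment / residualize -> paired inference, with all
## outputs written as CSV / GeoJSON plus a machine-readable run manifest.

#' Pipeline configuration
#'
#' Bundles the synthetic design with the analysis knobs: candidate alpha
#' grid, cleaning mode, CV observation level, PCA component cap,
#' residualization thresholds, and the master seed.
#'
#' @param synthetic a [synthetic_config()]; its seed is the master seed.
#' @param candidate_alphas ascending alpha grid in km; `NULL` scales the
#'   grid to each species' point cloud (see [estimate_range()]).
#' @param cleaning_mode `"strict"` (AND) or `"permissive"` (OR) for rule (a).
#' @param cv_level `"tree"` or `"leaf"`.
#' @param n_components PCA component cap for FDis.
#' @param screen_p,keep_p residualization thresholds.
#' @param sig_figs significant figures for printed range summaries.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            candidate_alphas = NULL,
                            cleaning_mode = c("strict", "permissive"),
                            cv_level = c("tree", "leaf"),
                            n_components = 5L,
                            screen_p = 0.1, keep_p = 0.05,
                            sig_figs = 2L) {
  cleaning_mode <- match.arg(cleaning_mode)
  cv_level <- match.arg(cv_level)
  if (!is.null(candidate_alphas) &&
      (is.unsorted(candidate_alphas) || any(candidate_alphas <= 0)))
    abort_validation("'candidate_alphas' must be ascending and positive")
  for (p in c(screen_p, keep_p))
    if (p <= 0 || p >= 1) abort_validation("thresholds must lie in (0, 1)")
  structure(list(synthetic = synthetic, candidate_alphas = candidate_alphas,
                 cleaning_mode = cleaning_mode, cv_level = cv_level,
                 n_components = check_count(n_components, "n_components"),
                 screen_p = screen_p, keep_p = keep_p,
                 sig_figs = check_count(sig_figs, "sig_figs")),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Generates traits, environments and occurrences from the configuration,
#' estimates every species' extent of occurrence (cleaning + alpha-shape),
#' computes variability profiles before and after environmental
#' residualization, and runs the paired congeneric tests and range-size
#' prediction models for every trait CV and for functional dispersion.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, all tables are written as
#'   CSV, ranges as GeoJSON, and a `manifest.json` with the seed, a config
#'   hash and per-file checksums is produced.
#' @return List of class `pipeline_result` with elements `traits`, `env`,
#'   `ranges` (data frame), `range_estimates`, `profile`,
#'   `profile_adjusted`, `env_cv`, `decomposition`, `paired_tests`,
#'   `prediction_models`, `pair_stats`, and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sc <- config$synthetic
  stage <- "simulate"
  result <- tryCatch({
    traits0 <- generate_trait_dataset(sc)
    envgen <- generate_env_table(traits0, sc$env_effects, sc$seed)
    env <- envgen$env; traits <- envgen$traits
    clim_cols <- grep("^clim", names(env), value = TRUE)
    pc1 <- climate_pc1(env[, clim_cols])
    env$climate_pc1 <- pc1$scores

    stage <- "range"
    meta <- unique(traits[, c("genus", "species", "pair", "range_class")])
    polys <- sc$range_polygons %||% default_range_polygons(meta, sc$seed)
    estimates <- lapply(meta$species, function(sp) {
      occ <- generate_occurrences(polys[[sp]], sc$n_occurrences,
                                  sc$outlier_fraction, sc$duplicate_fraction,
                                  seed = substream_seed(sc$seed, 100L + match(sp, meta$species)),
                                  species = sp)
      estimate_range(occ, config$candidate_alphas, mode = config$cleaning_mode)
    })
    names(estimates) <- meta$species
    ranges <- data.frame(meta,
                         eoo_km2 = vapply(estimates, function(r) r$eoo_km2, numeric(1)),
                         alpha = vapply(estimates, function(r) r$alpha, numeric(1)),
                         n_records_used = vapply(estimates, function(r)
                           r$n_records_used, integer(1)),
                         true_area_km2 = vapply(meta$species, function(sp)
                           polygon_area(polys[[sp]]), numeric(1)),
                         stringsAsFactors = FALSE)
    rownames(ranges) <- NULL

    stage <- "variability"
    profile <- species_variability_profile(traits, level = config$cv_level,
                                           n_components = config$n_components)
    decomposition <- lapply(all_traits(), function(tr)
      suppressWarnings(variance_decomposition(traits, tr)))
    names(decomposition) <- all_traits()

    stage <- "environment"
    ecv <- env_cv(env)
    adjusted <- suppressWarnings(
      residualize_traits(traits, env, config$screen_p, config$keep_p))
    profile_adj <- species_variability_profile(validate_adjusted(adjusted),
                                               level = "tree",
                                               n_components = config$n_components)

    stage <- "inference"
    paired <- run_paired_tests(profile, profile_adj)
    prediction <- run_prediction_models(profile, ranges)
    pair_stats <- pair_range_stats(ranges, config$sig_figs)

    list(traits = traits, env = env, ranges = ranges,
         range_estimates = estimates, profile = profile,
         profile_adjusted = profile_adj, env_cv = ecv,
         decomposition = decomposition, paired_tests = paired,
         prediction_models = prediction, pair_stats = pair_stats)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  result$manifest <- build_manifest(config)
  class(result) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_outputs(result, config, out_dir)
  result
}

validate_adjusted <- function(adjusted) {
  d <- adjusted
  d$leaf <- NA_character_
  class(d) <- c("trait_dataset", "data.frame")
  d
}

run_paired_tests <- function(profile, profile_adj) {
  meta <- profile$meta
  one_set <- function(prof, label) {
    per_metric <- lapply(split(prof$cv, prof$cv$trait), function(d) {
      v <- merge(d, meta, by = "species")
      v$value <- v$cv_corrected
      pd <- pair_deltas(v)
      paired_intercept_test(pd$delta, pd$genus,
                            metric = paste0(d$trait[1L], " CV", label))
    })
    fd <- data.frame(species = names(prof$fdis), value = unname(prof$fdis),
                     stringsAsFactors = FALSE)
    fd <- merge(fd, meta, by = "species")
    pd <- pair_deltas(fd)
    per_metric$FDis <- paired_intercept_test(pd$delta, pd$genus,
                                             metric = paste0("FDis", label))
    per_metric
  }
  raw <- one_set(profile, "")
  adj <- one_set(profile_adj, " (env-adjusted)")
  names(adj) <- paste0(names(adj), "_adjusted")
  c(raw, adj)
}

run_prediction_models <- function(profile, ranges) {
  meta <- ranges[, c("species", "genus", "eoo_km2")]
  models <- lapply(split(profile$cv, profile$cv$trait), function(d) {
    v <- merge(d, meta, by = "species")
    range_prediction_model(v$eoo_km2, v$cv_corrected, v$genus,
                           predictor_name = paste0(d$trait[1L], " CV"))
  })
  fd <- merge(data.frame(species = names(profile$fdis),
                         value = unname(profile$fdis), stringsAsFactors = FALSE),
              meta, by = "species")
  models$FDis <- range_prediction_model(fd$eoo_km2, fd$value, fd$genus,
                                        predictor_name = "FDis")
  models
}

build_manifest <- function(config) {
  cfg_json <- jsonlite::toJSON(rapply(unclass(config), unclass, how = "replace"),
                               auto_unbox = TRUE, digits = NA, force = TRUE)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  list(package = "traitrange",
       version = as.character(utils::packageVersion("traitrange")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       seed = config$synthetic$seed,
       config_hash = hash)
}

write_pipeline_outputs <- function(result, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_trait_csv(result$traits, p("traits.csv"))
  utils::write.csv(result$env, p("env.csv"), row.names = FALSE)
  utils::write.csv(result$profile$cv, p("cv.csv"), row.names = FALSE)
  utils::write.csv(data.frame(species = names(result$profile$fdis),
                              fdis = unname(result$profile$fdis)),
                   p("fdis.csv"), row.names = FALSE)
  decomp <- do.call(rbind, lapply(names(result$decomposition), function(tr) {
    d <- result$decomposition[[tr]]
    data.frame(trait = tr, level = names(d), proportion = as.numeric(d),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(decomp, p("decomposition.csv"), row.names = FALSE)
  utils::write.csv(result$ranges, p("ranges.csv"), row.names = FALSE)
  write_ranges_geojson(result$range_estimates, p("ranges.geojson"))
  utils::write.csv(result$env_cv, p("env_cv.csv"), row.names = FALSE)
  paired <- do.call(rbind, lapply(result$paired_tests, function(t)
    data.frame(metric = t$metric, n_pairs = t$n_pairs, intercept = t$intercept,
               se = t$se, genus_variance = t$genus_variance,
               lrt = t$lrt_statistic, p = t$p_value,
               fallback = t$fallback, stringsAsFactors = FALSE)))
  utils::write.csv(paired, p("paired_tests.csv"), row.names = FALSE)
  pred <- do.call(rbind, lapply(result$prediction_models, function(m)
    data.frame(predictor = m$predictor, slope = m$slope, se = m$slope_se,
               F_statistic = m$F_statistic, df_num = m$df_num,
               df_den = m$df_den, F_p = m$F_p, lrt = m$lrt_statistic,
               lrt_p = m$lrt_p, stringsAsFactors = FALSE)))
  utils::write.csv(pred, p("prediction_models.csv"), row.names = FALSE)
  cleaning <- do.call(rbind, lapply(result$range_estimates, function(r)
    data.frame(species = r$species, t(r$cleaning_report), stringsAsFactors = FALSE)))
  utils::write.csv(cleaning, p("cleaning_report.csv"), row.names = FALSE)
  manifest <- result$manifest
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "manifest.json"))
  manifest$files <- as.list(tools::md5sum(files))
  names(manifest$files) <- basename(names(manifest$files))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d species, %d pairs\n",
              nrow(x$ranges), nrow(x$pair_stats$per_pair)))
  cat(sprintf("  EOO recovery: median |error| %.2f%%\n",
              100 * stats::median(abs(x$ranges$eoo_km2 - x$ranges$true_area_km2) /
                                    x$ranges$true_area_km2)))
  sig <- sum(vapply(x$paired_tests, function(t) t$p_value < 0.05, logical(1)))
  cat(sprintf("  paired congeneric tests: %d of %d with p < 0.05\n",
              sig, length(x$paired_tests)))
  invisible(x)
}
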