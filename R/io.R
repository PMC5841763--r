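## Readers and writers for the tabular and geometric exchange formats:
## tidy trait CSV, occurrence CSV, GeoJSON polygons, and the bundled
## study table of 34 congeneric species with printed extents of occurrence.

#' Read a tidy trait CSV
#'
#' Expected columns: genus, species, pair, range_class, tree, trait, value,
#' and optionally leaf.  Validates positivity, range classes, and pair
#' completeness (each pair exactly one endemic and one widespread species).
#'
#' @param path CSV file path.
#' @return A validated `trait_dataset` data frame.
#' @export
read_trait_csv <- function(path) {
  if (!file.exists(path)) abort_validation("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genus", "species", "pair", "range_class", "tree", "trait", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort_validation("missing column(s): %s", paste(miss, collapse = ", "))
  if (!"leaf" %in% names(df)) df$leaf <- NA_character_
  validate_trait_dataset(df)
}

validate_trait_dataset <- function(df) {
  bad <- which(!is.finite(df$value) | df$value <= 0)
  if (length(bad))
    abort_validation("non-positive or missing trait value at row %d", bad[1L])
  bad <- which(!df$range_class %in% c("endemic", "widespread"))
  if (length(bad))
    abort_validation("unknown range class '%s' at row %d", df$range_class[bad[1L]], bad[1L])
  sp <- unique(df[, c("genus", "species", "pair", "range_class")])
  if (anyDuplicated(sp$species))
    abort_validation("species assigned to more than one genus/pair: %s",
                     sp$species[duplicated(sp$species)][1L])
  for (p in split(sp, sp$pair)) {
    if (nrow(p) != 2L || sort(p$range_class)[1L] != "endemic" ||
        sort(p$range_class)[2L] != "widespread")
      abort_validation("pair '%s' must have exactly one endemic and one widespread species",
                       p$pair[1L])
  }
  class(df) <- c("trait_dataset", "data.frame")
  attr(df, "units") <- trait_units()
  df
}

#' Write a tidy trait CSV
#' @param dataset a `trait_dataset`.
#' @param path output path.
#' @export
write_trait_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' Read an occurrence CSV
#'
#' Geographic files carry `decimalLongitude`/`decimalLatitude` (degrees),
#' planar files `x_km`/`y_km`; `locality_flag` and `record_id` are optional.
#' Coordinate bounds are enforced with the offending record id.
#'
#' @param path CSV file path.
#' @return An `occurrence_set`.
#' @export
read_occurrence_csv <- function(path) {
  if (!file.exists(path)) abort_validation("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"species" %in% names(df)) abort_validation("missing 'species' column")
  geo <- all(c("decimalLongitude", "decimalLatitude") %in% names(df))
  pla <- all(c("x_km", "y_km") %in% names(df))
  if (!geo && !pla)
    abort_validation("need decimalLongitude/decimalLatitude or x_km/y_km columns")
  ids <- if ("record_id" %in% names(df)) as.character(df$record_id) else
    sprintf("rec%05d", seq_len(nrow(df)))
  coords <- if (geo) cbind(df$decimalLongitude, df$decimalLatitude) else
    cbind(df$x_km, df$y_km)
  if (geo) {
    bad <- which(coords[, 2L] < -90 | coords[, 2L] > 90 |
                   coords[, 1L] < -180 | coords[, 1L] > 180 | !is.finite(coords[, 1L]) |
                   !is.finite(coords[, 2L]))
    if (length(bad))
      abort_validation("coordinate out of range for record '%s'", ids[bad[1L]])
  }
  occurrence_set(df$species[1L], coords,
                 if ("locality_flag" %in% names(df)) df$locality_flag else "ok",
                 mode = if (geo) "geographic" else "planar", record_id = ids)
}

#' Write an occurrence CSV
#' @param occ an `occurrence_set`.
#' @param path output path.
#' @export
write_occurrence_csv <- function(occ, path) {
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE)
  invisible(path)
}

#' Write range polygons as GeoJSON
#'
#' One Feature per range estimate; alpha-shape boundary rings become
#' Polygon/MultiPolygon geometries.  When a range was estimated from
#' geographic records the rings are back-projected to WGS84 longitude /
#' latitude; planar (synthetic) ranges are written in their km coordinates.
#'
#' @param ranges a `range_estimate` or list of them.
#' @param path output path.
#' @export
write_ranges_geojson <- function(ranges, path) {
  if (inherits(ranges, "range_estimate")) ranges <- list(ranges)
  features <- lapply(ranges, function(r) {
    rings <- lapply(r$shape$rings, function(ring) {
      if (!is.null(r$projection_centre))
        ring <- laea_inverse(ring, r$projection_centre)
      unname(lapply(seq_len(nrow(ring) + 1L), function(i) {
        j <- if (i > nrow(ring)) 1L else i
        as.numeric(ring[j, ])
      }))
    })
    geometry <- if (length(rings) <= 1L)
      list(type = "Polygon", coordinates = rings)
    else
      list(type = "MultiPolygon", coordinates = lapply(rings, list))
    list(type = "Feature",
         properties = list(species = r$species, alpha_km = r$alpha,
                           eoo_km2 = r$eoo_km2,
                           n_records_used = r$n_records_used),
         geometry = geometry)
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read the first polygon from a GeoJSON file
#'
#' Returns the outer ring of the first Polygon/MultiPolygon feature as a
#' two-column coordinate matrix (used for land masks and stored true
#' ranges).
#'
#' @param path GeoJSON file path.
#' @return Two-column coordinate matrix (closing vertex dropped).
#' @export
read_polygon_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  geom <- if (identical(gj$type, "FeatureCollection")) gj$features[[1L]]$geometry
  else if (identical(gj$type, "Feature")) gj$geometry else gj
  coords <- switch(geom$type,
                   Polygon = geom$coordinates[[1L]],
                   MultiPolygon = geom$coordinates[[1L]][[1L]],
                   abort_validation("unsupported geometry type '%s'", geom$type))
  m <- do.call(rbind, lapply(coords, function(p) as.numeric(unlist(p))))
  if (nrow(m) > 1L && all(m[1L, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  m
}

#' The bundled study table: 34 species, 17 congeneric pairs
#'
#' Species list of the Costa Rican endemic/widespread tree-pair system with
#' range-size class, number of sampled trees and printed extent of
#' occurrence (km^2).  The two pairs inside each of the three four-species
#' genera follow the published pairing where stated and range-size rank
#' otherwise; all-combination statistics in [pair_range_stats()] do not
#' depend on that choice.
#'
#' @return Data frame with columns family, genus, species, pair,
#'   range_class, n_trees, eoo_km2.
#' @export
study_species_table <- function() {
  path <- system.file("extdata", "costa_rica_tree_ranges.csv",
                      package = "traitrange", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
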