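## Occurrence cleaning and extent-of-occurrence (EOO) estimation.
##
## The workflow mirrors standard range-size practice for herbarium/GBIF
## records: (a) drop spatial outliers whose nearest neighbour is at least
## twice the mean pairwise distance and whose locality metadata is suspicious
## (planted in parks or gardens), (b) collapse duplicates inside the same
## 1x1 km grid cell, (c) drop records without locality detail; then build an
## alpha-shape around the retained points under an equal-area projection and
## report its area (optionally intersected with a land mask) in km^2.

#' Construct an occurrence set
#'
#' @param species single species identifier.
#' @param coords two-column matrix or data frame; `lon`/`lat` in degrees for
#'   geographic mode, `x_km`/`y_km` for planar mode.
#' @param locality_flag character vector, one of `"ok"`, `"suspicious"`,
#'   `"missing_locality"`; recycled.
#' @param mode `"geographic"` or `"planar"`.
#' @param record_id optional stable record identifiers (unique).
#' @return data frame of class `occurrence_set` with attribute `coord_mode`.
#' @export
occurrence_set <- function(species, coords, locality_flag = "ok",
                           mode = c("planar", "geographic"),
                           record_id = NULL) {
  mode <- match.arg(mode)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (any(!is.finite(coords))) abort_validation("coordinates must be finite")
  if (mode == "geographic") {
    if (any(coords[, 1L] < -180 | coords[, 1L] > 180))
      abort_validation("longitude out of [-180, 180]")
    if (any(coords[, 2L] < -90 | coords[, 2L] > 90))
      abort_validation("latitude out of [-90, 90]")
  }
  record_id <- record_id %||% sprintf("rec%05d", seq_len(n))
  if (anyDuplicated(record_id)) abort_validation("record ids must be unique")
  locality_flag <- rep_len(as.character(locality_flag), n)
  bad <- setdiff(unique(locality_flag), c("ok", "suspicious", "missing_locality"))
  if (length(bad)) abort_validation("unknown locality_flag: %s", bad[1L])
  df <- data.frame(species = as.character(species), record_id = record_id,
                   stringsAsFactors = FALSE)
  if (mode == "geographic") {
    df$decimalLongitude <- coords[, 1L]; df$decimalLatitude <- coords[, 2L]
  } else {
    df$x_km <- coords[, 1L]; df$y_km <- coords[, 2L]
  }
  df$locality_flag <- locality_flag
  structure(df, class = c("occurrence_set", "data.frame"), coord_mode = mode)
}

coord_mode <- function(occ) attr(occ, "coord_mode") %||% "planar"

occ_coords <- function(occ) {
  if (coord_mode(occ) == "geographic")
    cbind(occ$decimalLongitude, occ$decimalLatitude)
  else cbind(occ$x_km, occ$y_km)
}

occ_subset <- function(occ, keep) {
  out <- occ[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "coord_mode") <- coord_mode(occ)
  class(out) <- c("occurrence_set", "data.frame")
  out
}

#' Mean pairwise distance between records
#'
#' Arithmetic mean over all unordered pairs; great-circle (haversine, km) in
#' geographic mode, Euclidean in planar mode.
#'
#' @param x an `occurrence_set` or a two-column coordinate matrix.
#' @param mode coordinate mode when `x` is a bare matrix.
#' @return Mean pairwise distance in km.
#' @export
mean_pairwise_distance <- function(x, mode = NULL) {
  if (inherits(x, "occurrence_set")) {
    mode <- coord_mode(x); pts <- occ_coords(x)
  } else {
    pts <- as.matrix(x); mode <- mode %||% "planar"
  }
  if (nrow(pts) < 2L)
    abort_validation("mean_pairwise_distance needs at least 2 points")
  d <- pairwise_distances(pts, mode)
  mean(d[upper.tri(d)])
}

pairwise_distances <- function(pts, mode) {
  if (mode == "geographic") geosphere::distm(pts, fun = geosphere::distHaversine) / 1000
  else as.matrix(stats::dist(pts))
}

#' Flag distance outliers (cleaning rule a)
#'
#' A record is flagged when its nearest-neighbour distance is at least
#' `factor` times the mean pairwise distance between all records and
#' (in `"strict"` mode) its locality metadata is suspicious; `"permissive"`
#' mode uses OR instead of AND.
#'
#' @param occ an `occurrence_set`.
#' @param factor distance multiplier (default 2).
#' @param mode `"strict"` (AND, default) or `"permissive"` (OR).
#' @return Logical vector of flags, one per record.
#' @export
flag_distance_outliers <- function(occ, factor = 2, mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  n <- nrow(occ)
  if (n < 3L) {
    warning("fewer than 3 records: no distance-outlier flagging applied")
    return(logical(n))
  }
  d <- pairwise_distances(occ_coords(occ), coord_mode(occ))
  diag(d) <- Inf
  nn <- unname(apply(d, 1L, min))
  mpd <- mean(d[upper.tri(d)])
  far <- nn >= factor * mpd
  suspicious <- occ$locality_flag == "suspicious"
  if (mode == "strict") far & suspicious else far | suspicious
}

#' Grid deduplication (cleaning rule b)
#'
#' Keeps at most one record per `cell_km` x `cell_km` grid cell (grid
#' anchored at the projection origin); ties broken by smallest record id.
#'
#' @param occ a planar-mode `occurrence_set`.
#' @param cell_km cell size in km (default 1).
#' @return The deduplicated `occurrence_set`.
#' @export
dedupe_grid <- function(occ, cell_km = 1) {
  if (coord_mode(occ) != "planar")
    abort_validation("dedupe_grid needs planar (projected) coordinates; project first")
  cell <- paste(floor(occ$x_km / cell_km), floor(occ$y_km / cell_km))
  ord <- order(cell, occ$record_id)
  keep_sorted <- !duplicated(cell[ord])
  keep <- sort(ord[keep_sorted])
  occ_subset(occ, keep)
}

#' Drop records without locality detail (cleaning rule c)
#'
#' @param occ an `occurrence_set`.
#' @return `occurrence_set` without `missing_locality` records; warns when
#'   nothing survives.
#' @export
drop_missing_locality <- function(occ) {
  keep <- occ$locality_flag != "missing_locality"
  if (!any(keep)) warning("all records lack locality information")
  occ_subset(occ, keep)
}

#' Lambert azimuthal equal-area projection of occurrences
#'
#' Projects geographic records to planar km, centred on the occurrence
#' centroid (minimising distortion for the species' own extent); planar
#' input is passed through unchanged.
#'
#' @param occ an `occurrence_set`.
#' @param centre optional `c(lon, lat)` projection centre; defaults to the
#'   coordinate centroid.
#' @return Planar `occurrence_set` with attribute `projection_centre`.
#' @export
project_equal_area <- function(occ, centre = NULL) {
  if (coord_mode(occ) == "planar") return(occ)
  ll <- occ_coords(occ)
  centre <- centre %||% colMeans(ll)
  xy <- laea_forward(ll, centre)
  out <- occurrence_set(occ$species[1L], xy, occ$locality_flag,
                        mode = "planar", record_id = occ$record_id)
  attr(out, "projection_centre") <- centre
  out
}

laea_forward <- function(lonlat, centre) {
  lam <- lonlat[, 1L] * pi / 180; phi <- lonlat[, 2L] * pi / 180
  lam0 <- centre[1L] * pi / 180; phi0 <- centre[2L] * pi / 180
  g <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  if (any(g < 1e-10))
    abort_validation("projection undefined at the antipode of the centre")
  kp <- sqrt(2 / g)
  cbind(x_km = EARTH_RADIUS_KM * kp * cos(phi) * sin(lam - lam0),
        y_km = EARTH_RADIUS_KM * kp *
          (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0)))
}

laea_inverse <- function(xy, centre) {
  x <- xy[, 1L] / EARTH_RADIUS_KM; y <- xy[, 2L] / EARTH_RADIUS_KM
  lam0 <- centre[1L] * pi / 180; phi0 <- centre[2L] * pi / 180
  rho <- sqrt(x^2 + y^2)
  c_ang <- 2 * asin(pmin(1, rho / 2))
  phi <- ifelse(rho < 1e-12, phi0,
                asin(cos(c_ang) * sin(phi0) + y * sin(c_ang) * cos(phi0) / rho))
  lam <- lam0 + atan2(x * sin(c_ang),
                      rho * cos(phi0) * cos(c_ang) - y * sin(phi0) * sin(c_ang))
  lam[rho < 1e-12] <- lam0
  cbind(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

#' Full occurrence-cleaning pass (rules a, b, c)
#'
#' Projects geographic input to planar km, then applies distance-outlier
#' removal, 1-km grid deduplication and missing-locality removal, recording
#' removal counts per rule.
#'
#' @inheritParams flag_distance_outliers
#' @param cell_km dedupe cell size in km.
#' @return Cleaned planar `occurrence_set` with attribute `cleaning_report`
#'   (named counts removed per rule, plus the flagging mode).
#' @export
clean_occurrences <- function(occ, factor = 2, mode = c("strict", "permissive"),
                              cell_km = 1) {
  mode <- match.arg(mode)
  occ <- project_equal_area(occ)
  n0 <- nrow(occ)
  flags <- if (n0 >= 3L) flag_distance_outliers(occ, factor, mode) else logical(n0)
  occ1 <- occ_subset(occ, !flags)
  occ2 <- dedupe_grid(occ1, cell_km)
  occ3 <- drop_missing_locality(occ2)
  attr(occ3, "cleaning_report") <- c(
    rule_a_outliers = n0 - nrow(occ1),
    rule_b_duplicates = nrow(occ1) - nrow(occ2),
    rule_c_missing_locality = nrow(occ2) - nrow(occ3),
    mode = mode)
  occ3
}

#' Select the smallest adequate alpha
#'
#' Returns the smallest candidate alpha whose alpha-shape is a valid,
#' non-degenerate (multi)polygon containing every point (boundary included);
#' falls back to the convex hull (`alpha = Inf`) with a warning when no
#' candidate qualifies.
#'
#' @param pts two-column matrix of planar points (km).
#' @param candidate_alphas ascending vector of candidate alpha values (km).
#' @return List with `alpha`, the corresponding `shape` (class
#'   [alpha_shape()]), and `fallback` (logical).
#' @export
select_alpha <- function(pts, candidate_alphas) {
  if (!length(candidate_alphas) || is.unsorted(candidate_alphas))
    abort_validation("'candidate_alphas' must be non-empty and ascending")
  pts <- unique(as.matrix(pts))
  for (a in candidate_alphas) {
    sh <- alpha_shape(pts, a)
    if (alpha_shape_covers_all(sh)) {
      return(list(alpha = a, shape = sh, fallback = FALSE))
    }
  }
  warning("no candidate alpha covers all points; falling back to the convex hull")
  list(alpha = Inf, shape = alpha_shape(pts, Inf), fallback = TRUE)
}

## Every point of a Delaunay triangulation is covered by the kept triangle
## union iff it is a vertex of at least one kept triangle.
alpha_shape_covers_all <- function(shape) {
  nrow(shape$triangles) > 0 &&
    length(unique(as.integer(shape$triangles))) == nrow(shape$points)
}

#' Extent of occurrence from an alpha-shape
#'
#' Area in km^2 of the shape, optionally intersected with a (convex) land
#' polygon; the intersection clips each retained Delaunay triangle against
#' the land polygon, so concave or disconnected alpha-shapes are handled.
#'
#' @param shape an [alpha_shape()] object or a simple-polygon coordinate
#'   matrix (planar km).
#' @param land optional convex land polygon (two-column matrix, planar km).
#' @return Area in km^2.
#' @export
eoo_area <- function(shape, land = NULL) {
  if (!is.null(land)) {
    land <- as.matrix(land)
    if (nrow(land) < 3L || !is_convex_polygon(land))
      abort_validation("land mask must be a convex polygon (>= 3 vertices)")
  }
  if (inherits(shape, "alpha_shape")) {
    if (!nrow(shape$triangles)) return(0)
    tri_area <- function(tr) {
      poly <- shape$points[tr, , drop = FALSE]
      if (is.null(land)) polygon_area(poly)
      else polygon_area(clip_polygon_convex(poly, land))
    }
    sum(vapply(seq_len(nrow(shape$triangles)),
               function(i) tri_area(shape$triangles[i, ]), numeric(1)))
  } else {
    poly <- as.matrix(shape)
    if (is.null(land)) polygon_area(poly)
    else polygon_area(clip_polygon_convex(poly, land))
  }
}

#' Estimate a species' range size end-to-end
#'
#' Cleans the records, selects the smallest adequate alpha from a candidate
#' grid, and returns the alpha-shape EOO in km^2.
#'
#' @param occ an `occurrence_set` (geographic or planar).
#' @param candidate_alphas ascending candidate alpha grid in km; `NULL`
#'   (default) uses a geometric grid from 1/4 to 2 times the cloud's
#'   diameter, so the smallest adequate alpha is found at any range scale.
#' @param land optional convex land polygon (planar km).
#' @param factor,mode,cell_km cleaning parameters, see [clean_occurrences()].
#' @return Object of class `range_estimate`: species, selected `alpha`,
#'   `shape`, `eoo_km2`, `n_records_used`, `cleaning_report`.
#' @export
estimate_range <- function(occ, candidate_alphas = NULL,
                           land = NULL, factor = 2,
                           mode = c("strict", "permissive"), cell_km = 1) {
  mode <- match.arg(mode)
  cleaned <- clean_occurrences(occ, factor, mode, cell_km)
  pts <- occ_coords(cleaned)
  if (nrow(unique(pts)) < 3L)
    abort_validation("species '%s': fewer than 3 distinct records after cleaning",
                     occ$species[1L])
  ## default grid scales with the cloud so one setting works across species
  ## whose extents span orders of magnitude; the diam/4 floor separates
  ## genuinely disjunct clusters without eroding contiguous range boundaries
  candidate_alphas <- candidate_alphas %||%
    (max(stats::dist(pts[grDevices::chull(pts), , drop = FALSE])) * 2^seq(-2, 1))
  sel <- select_alpha(pts, candidate_alphas)
  structure(list(species = occ$species[1L],
                 alpha = sel$alpha,
                 shape = sel$shape,
                 alpha_fallback = sel$fallback,
                 eoo_km2 = eoo_area(sel$shape, land),
                 n_records_used = nrow(cleaned),
                 cleaning_report = attr(cleaned, "cleaning_report"),
                 projection_centre = attr(cleaned, "projection_centre")),
            class = "range_estimate")
}

#' @export
print.range_estimate <- function(x, ...) {
  cat(sprintf("Range estimate for %s\n", x$species))
  cat(sprintf("  alpha = %g km%s, EOO = %.4g km^2, records used = %d\n",
              x$alpha, if (x$alpha_fallback) " (convex-hull fallback)" else "",
              x$eoo_km2, x$n_records_used))
  rep <- x$cleaning_report
  cat(sprintf("  removed: %s outliers (rule a), %s in-cell duplicates (rule b), %s without locality (rule c)\n",
              rep[["rule_a_outliers"]], rep[["rule_b_duplicates"]],
              rep[["rule_c_missing_locality"]]))
  invisible(x)
}

#' Paired range-size summaries
#'
#' Per congeneric pair, the widespread-minus-endemic EOO difference and the
#' widespread/endemic ratio; plus the overall minimum/maximum difference and
#' the minimum/maximum ratio over *all* within-genus endemic-widespread
#' combinations (robust to how the pairs were drawn in genera with more than
#' one pair).
#'
#' @param table data frame with columns `species`, `genus`, `pair`,
#'   `range_class` (`"endemic"`/`"widespread"`), `eoo_km2`.
#' @param sig_figs significant figures used in the printed summary (default 2).
#' @return List of class `pair_range_stats` with elements `per_pair`,
#'   `combinations`, and `summary` (min/max delta and ratio, rounded to
#'   `sig_figs` significant figures).
#' @export
pair_range_stats <- function(table, sig_figs = 2) {
  need <- c("species", "genus", "pair", "range_class", "eoo_km2")
  miss <- setdiff(need, names(table))
  if (length(miss)) abort_validation("missing column(s): %s", paste(miss, collapse = ", "))
  per_pair <- do.call(rbind, lapply(split(table, table$pair), function(d) {
    w <- d[d$range_class == "widespread", , drop = FALSE]
    e <- d[d$range_class == "endemic", , drop = FALSE]
    if (nrow(w) != 1L || nrow(e) != 1L)
      abort_validation("pair '%s' must have exactly one endemic and one widespread member",
                       d$pair[1L])
    data.frame(pair = d$pair[1L], genus = d$genus[1L],
               widespread = w$species, endemic = e$species,
               eoo_widespread = w$eoo_km2, eoo_endemic = e$eoo_km2,
               delta = w$eoo_km2 - e$eoo_km2,
               ratio = w$eoo_km2 / e$eoo_km2,
               stringsAsFactors = FALSE)
  }))
  rownames(per_pair) <- NULL
  combos <- do.call(rbind, lapply(split(table, table$genus), function(d) {
    w <- d[d$range_class == "widespread", , drop = FALSE]
    e <- d[d$range_class == "endemic", , drop = FALSE]
    if (!nrow(w) || !nrow(e)) return(NULL)
    g <- expand.grid(wi = seq_len(nrow(w)), ei = seq_len(nrow(e)))
    data.frame(genus = d$genus[1L],
               widespread = w$species[g$wi], endemic = e$species[g$ei],
               delta = w$eoo_km2[g$wi] - e$eoo_km2[g$ei],
               ratio = w$eoo_km2[g$wi] / e$eoo_km2[g$ei],
               stringsAsFactors = FALSE)
  }))
  rownames(combos) <- NULL
  summary <- list(
    min_delta = signif(min(per_pair$delta), sig_figs),
    max_delta = signif(max(per_pair$delta), sig_figs),
    min_ratio = signif(min(combos$ratio), sig_figs),
    max_ratio = signif(max(combos$ratio), sig_figs))
  structure(list(per_pair = per_pair, combinations = combos, summary = summary),
            class = "pair_range_stats")
}

#' @export
print.pair_range_stats <- function(x, ...) {
  cat(sprintf("%d congeneric pairs\n", nrow(x$per_pair)))
  cat(sprintf("  EOO difference (widespread - endemic): min %g, max %g km^2\n",
              x$summary$min_delta, x$summary$max_delta))
  cat(sprintf("  EOO ratio over within-genus combinations: min %g, max %g\n",
              x$summary$min_ratio, x$summary$max_ratio))
  invisible(x)
}
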