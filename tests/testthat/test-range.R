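test_that("mean pairwise distance matches hand-computed and brute-force values", {
  expect_equal(mean_pairwise_distance(rbind(c(0, 0), c(0, 1))), 1.0)
  # collinear x = 0, 1, 2: pair distances {1, 2, 1}
  expect_equal(mean_pairwise_distance(cbind(c(0, 1, 2), 0)), 4 / 3)
  set.seed(3)
  pts <- cbind(runif(40), runif(40))
  expect_equal(mean_pairwise_distance(pts), oracle_mean_pairwise(pts))
  expect_error(mean_pairwise_distance(cbind(1, 1)), "at least 2")
})

test_that("great-circle distances are used in geographic mode", {
  occ <- occurrence_set("sp", cbind(c(0, 1), c(0, 0)), mode = "geographic")
  # one degree of longitude at the equator on the haversine sphere
  expect_equal(mean_pairwise_distance(occ), 2 * pi * 6378.137 / 360, tolerance = 1e-6)
})

test_that("distance-outlier flagging finds exactly the planted point (brute-force NN oracle)", {
  grid <- as.matrix(expand.grid(0:2, 0:2))  # compact 9-point cluster
  far <- c(40, 40)
  pts <- rbind(grid, far)
  occ <- occurrence_set("sp", pts, c(rep("ok", 9), "suspicious"), mode = "planar")
  flags <- flag_distance_outliers(occ, factor = 2, mode = "strict")
  nn <- oracle_nn(pts)
  mpd <- oracle_mean_pairwise(pts)
  expect_identical(flags, nn >= 2 * mpd & occ$locality_flag == "suspicious")
  expect_identical(which(flags), 10L)
  # without the suspicious flag, strict mode keeps the point but permissive drops it
  occ_ok <- occurrence_set("sp", pts, "ok", mode = "planar")
  expect_false(any(flag_distance_outliers(occ_ok, mode = "strict")))
  expect_true(flag_distance_outliers(occ_ok, mode = "permissive")[10])
})

test_that("symmetric configurations and infinite factors produce no flags", {
  theta <- 2 * pi * (0:7) / 8
  occ <- occurrence_set("sp", cbind(cos(theta), sin(theta)), "suspicious")
  expect_false(any(flag_distance_outliers(occ)))
  expect_false(any(flag_distance_outliers(occ, factor = Inf)))
  two <- occurrence_set("sp", rbind(c(0, 0), c(5, 5)), "suspicious")
  expect_warning(f <- flag_distance_outliers(two), "fewer than 3")
  expect_false(any(f))
})

test_that("grid dedupe keeps one lowest-id record per cell (bucketing oracle)", {
  near <- occurrence_set("sp", rbind(c(0.5, 0.5), c(0.505, 0.5)))
  expect_identical(nrow(dedupe_grid(near)), 1L)
  centres <- occurrence_set("sp", as.matrix(expand.grid(0:4 + 0.5, 0:4 + 0.5)))
  expect_identical(nrow(dedupe_grid(centres)), 25L)
  set.seed(9)
  x <- runif(100, 0, 6); y <- runif(100, 0, 6)
  occ <- occurrence_set("sp", cbind(x, y))
  kept <- dedupe_grid(occ)
  expect_setequal(kept$record_id, oracle_dedupe_ids(x, y, occ$record_id))
})

test_that("missing-locality removal counts correctly and warns on empty output", {
  occ <- occurrence_set("sp", cbind(runif(10), runif(10)),
                        rep(c("ok", "missing_locality"), 5))
  expect_identical(nrow(drop_missing_locality(occ)), 5L)
  all_ok <- occurrence_set("sp", cbind(runif(4), runif(4)), "ok")
  expect_identical(drop_missing_locality(all_ok)$record_id, all_ok$record_id)
  all_missing <- occurrence_set("sp", cbind(runif(4), runif(4)), "missing_locality")
  expect_warning(out <- drop_missing_locality(all_missing), "locality")
  expect_identical(nrow(out), 0L)
})

test_that("equal-area projection is centred, area-preserving, and passes planar input through", {
  ll <- cbind(c(-83.5, -83.3, -83.4), c(8.5, 8.7, 8.3))
  occ <- occurrence_set("sp", ll, mode = "geographic")
  proj <- project_equal_area(occ)
  centre_xy <- traitrange:::laea_forward(rbind(colMeans(ll)), colMeans(ll))
  expect_equal(as.numeric(centre_xy), c(0, 0), tolerance = 1e-12)
  # 1 deg x 1 deg quadrilateral near the equator vs geodesic oracle area
  quad <- cbind(c(10, 11, 11, 10), c(0, 0, 1, 1))
  quad_occ <- occurrence_set("sp", quad, mode = "geographic")
  proj_quad <- project_equal_area(quad_occ)
  area_proj <- polygon_area(cbind(proj_quad$x_km, proj_quad$y_km))
  area_geo <- geosphere::areaPolygon(quad) / 1e6
  expect_equal(area_proj, area_geo, tolerance = 0.01)
  planar <- occurrence_set("sp", cbind(1:3, 3:1), mode = "planar")
  expect_identical(project_equal_area(planar), planar)
  # inverse projection round-trips
  back <- traitrange:::laea_inverse(cbind(proj$x_km, proj$y_km), colMeans(ll))
  expect_equal(unname(back), unname(ll), tolerance = 1e-9)
})

test_that("alpha selection returns the smallest covering candidate (exhaustive oracle)", {
  tr <- rbind(c(0, 0), c(4, 0), c(0, 3))  # circumradius 2.5
  sel <- select_alpha(tr, c(0.1, 50))
  expect_equal(sel$alpha, 50)
  expect_false(sel$fallback)
  set.seed(13)
  pts <- cbind(runif(80, 0, 10), runif(80, 0, 10))
  cands <- c(0.5, 1, 2, 4, 8, 16)
  sel <- select_alpha(pts, cands)
  covering <- sapply(cands, function(a)
    traitrange:::alpha_shape_covers_all(alpha_shape(pts, a)))
  expect_equal(sel$alpha, cands[which(covering)[1]])
  # when nothing covers, fall back to the hull with a warning
  expect_warning(fb <- select_alpha(pts, 0.01), "convex hull")
  expect_true(fb$fallback)
  expect_equal(fb$shape$area, polygon_area(pts[chull(pts), ]), tolerance = 1e-12)
})

test_that("EOO area handles land masks analytically", {
  unit <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(eoo_area(unit), 1.0)
  land <- rbind(c(0.5, -1), c(5, -1), c(5, 2), c(0.5, 2))
  expect_equal(eoo_area(unit, land), 0.5)
  sh <- alpha_shape(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), Inf)
  expect_equal(eoo_area(sh), 1.0)
  expect_equal(eoo_area(sh, land), 0.5)
  expect_error(eoo_area(unit, rbind(c(0, 0), c(2, 0), c(0.1, 0.1), c(0, 2))), "convex")
})

test_that("the full cleaning pass is idempotent on generated data", {
  poly <- rbind(c(0, 0), c(60, 0), c(60, 40), c(0, 40))
  occ <- generate_occurrences(poly, 300, 0.03, 0.1, seed = 4, species = "sp")
  once <- clean_occurrences(occ)
  twice <- clean_occurrences(once)
  expect_identical(once$record_id, twice$record_id)
  expect_equal(cbind(once$x_km, once$y_km), cbind(twice$x_km, twice$y_km))
})

test_that("pair range statistics validate structure and handle ties", {
  tab <- data.frame(species = c("a", "b", "c", "d"),
                    genus = c("G1", "G1", "G2", "G2"),
                    pair = c("P1", "P1", "P2", "P2"),
                    range_class = c("endemic", "widespread", "endemic", "widespread"),
                    eoo_km2 = c(10, 10, 5, 50))
  st <- pair_range_stats(tab)
  expect_equal(st$per_pair$delta[st$per_pair$pair == "P1"], 0)
  expect_equal(st$per_pair$ratio[st$per_pair$pair == "P1"], 1)
  expect_equal(st$per_pair$ratio[st$per_pair$pair == "P2"], 10)
  broken <- tab; broken$range_class[2] <- "endemic"
  expect_error(pair_range_stats(broken), "P1")
})
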