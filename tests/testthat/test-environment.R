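test_that("climate ordination axis is shifted to zero minimum and captures dominant factors", {
  set.seed(41)
  # six perfectly correlated variables: one axis carries everything
  base <- rnorm(30)
  perfect <- sapply(1:6, function(j) j * base + j)
  p <- climate_pc1(perfect)
  expect_equal(p$explained, 1.0)
  expect_identical(min(p$scores), 0)
  # one dominant factor with loading lambda on each standardized variable:
  # the leading eigenvalue of the correlation matrix is (1 + 5 lambda^2) / 6
  lambda <- 0.9; n <- 4000
  f <- rnorm(n)
  clim <- sapply(1:6, function(j) lambda * f + sqrt(1 - lambda^2) * rnorm(n))
  p2 <- climate_pc1(clim)
  analytic <- (1 + 5 * lambda^2) / 6
  expect_lt(abs(p2$explained - analytic) / analytic, 0.02)
  bad <- clim; bad[, 3] <- 7
  expect_error(climate_pc1(bad), "zero-variance")
})

test_that("environmental CVs use the corrected formula and flag undefined cases", {
  env <- data.frame(tree = sprintf("t%d", 1:8),
                    species = rep(c("a", "b"), each = 4),
                    climate_pc1 = c(1, 1, 3, 3, 1, 1, 3, 3),
                    slope = c(10, 10, 10, 10, 0, 0, 0, 0),
                    light = c(1, 1, 3, 3, 1, 1, 3, 3))
  expect_warning(out <- env_cv(env), "undefined")
  a_light <- out$cv_corrected[out$species == "a" & out$variable == "light"]
  expect_equal(a_light, sd(c(1, 1, 3, 3)) / 2 * (1 + 1 / 16))
  # identical multisets give identical CVs (permutation invariance)
  expect_equal(out$cv_corrected[out$species == "b" & out$variable == "light"], a_light)
  # species b: slope identically zero -> NA, not silently 0
  expect_true(is.na(out$cv_corrected[out$species == "b" & out$variable == "slope"]))
  # a single shared site gives all-zero variation
  one_site <- data.frame(tree = sprintf("t%d", 1:3), species = "c",
                         climate_pc1 = 2, slope = 5, light = 3)
  expect_true(all(env_cv(one_site)$cv_corrected == 0))
})

make_env_for <- function(tm, climate, light = NULL, slope = NULL) {
  trees <- unique(tm$tree)
  n <- length(trees)
  data.frame(tree = trees,
             climate_pc1 = climate,
             light = light %||% rep(2, n),
             slope = slope %||% rep(10, n))
}

test_that("a noiseless linear trait collapses to its mean after residualization", {
  cfg <- synthetic_config(n_genera = 1, pairs_per_genus = 1, trees_per_species = 20,
                          leaves_per_tree = 1,
                          variance_components = c(genus = 0, species = 0, tree = 0, leaf = 0),
                          seed = 2)
  d <- generate_trait_dataset(cfg)
  tm <- tree_means(d)
  clim <- seq(0, 3, length.out = length(unique(tm$tree)))
  env <- make_env_for(tm, clim)
  i <- match(tm$tree, env$tree)
  d2 <- tm
  d2$value <- d2$value + 2 * env$climate_pc1[i]   # exact linear dependence
  class(d2) <- c("trait_dataset", "data.frame")
  # a zero-noise fit is the point here; silence R's perfect-fit warnings
  adj <- suppressWarnings(residualize_traits(d2, env))
  for (tr in unique(adj$trait)) {
    sub <- adj[adj$trait == tr & adj$species == adj$species[1], ]
    expect_equal(sub$value, rep(mean(sub$value), nrow(sub)), tolerance = 1e-9)
    expect_true(all(sub$adjusted == "climate_pc1"))
  }
})

test_that("residualization preserves trait means exactly and recovers injected noise variance", {
  set.seed(9)
  n <- 500
  cfg <- synthetic_config(n_genera = 1, pairs_per_genus = 1, trees_per_species = n,
                          leaves_per_tree = 1,
                          variance_components = c(genus = 0, species = 0, tree = 0, leaf = 0),
                          seed = 3)
  tm <- tree_means(generate_trait_dataset(cfg))
  env <- make_env_for(tm, rnorm(length(unique(tm$tree)), 2, 1))
  i <- match(tm$tree, env$tree)
  noise_sd <- 0.3
  d2 <- tm
  sel <- d2$trait == "WSG"
  d2$value[sel] <- d2$value[sel] + 1.5 * env$climate_pc1[i][sel] +
    rnorm(sum(sel), 0, noise_sd)
  class(d2) <- c("trait_dataset", "data.frame")
  # constant traits other than WSG fit perfectly; silence those warnings
  adj <- suppressWarnings(residualize_traits(d2, env))
  for (tr in unique(adj$trait)) {
    expect_equal(mean(adj$value[adj$trait == tr]), mean(d2$value[d2$trait == tr]))
  }
  got_var <- var(adj$value[adj$trait == "WSG"])
  expect_lt(abs(got_var - noise_sd^2) / noise_sd^2, 0.10)
})

test_that("residualization is exactly idempotent once all covariates are regressed out", {
  set.seed(15)
  n <- 60
  cfg <- synthetic_config(n_genera = 1, pairs_per_genus = 1, trees_per_species = n,
                          leaves_per_tree = 1,
                          variance_components = c(genus = 0, species = 0,
                                                  tree = 0.0001, leaf = 0),
                          seed = 4)
  tm <- tree_means(generate_trait_dataset(cfg))
  trees <- unique(tm$tree)
  env <- data.frame(tree = trees, climate_pc1 = rnorm(n * 2, 2, 1),
                    light = sample(0:5, n * 2, TRUE), slope = abs(rnorm(n * 2, 15, 8)))
  i <- match(tm$tree, env$tree)
  d2 <- tm
  # strong effects on all three covariates so every one is screened and kept;
  # residuals are then orthogonal to all of them, and a second pass finds
  # exactly nothing to remove
  d2$value <- d2$value * (1 + 0.2 * env$climate_pc1[i] + 0.3 * env$light[i] +
                            0.05 * env$slope[i])
  class(d2) <- c("trait_dataset", "data.frame")
  once <- residualize_traits(d2, env)
  expect_true(all(once$adjusted == "climate_pc1,light,slope"))
  class(once) <- c("trait_dataset", "data.frame")
  twice <- residualize_traits(once, env)
  expect_equal(twice$value, once$value, tolerance = 1e-10)
  expect_true(all(twice$adjusted == ""))
})

test_that("under the null, most trait-species combinations are left untouched", {
  # retention requires a univariate p < 0.1 followed by p < 0.05 in the joint
  # model; for a single screened covariate these events nest, so per covariate
  # P(retained) <= 0.05 and P(any of 3) is about 1 - 0.95^3 = 0.143.  The
  # expected untouched fraction is therefore about 0.857; we check a
  # conservative lower bound well above chance but below that expectation.
  unchanged <- unlist(lapply(1:25, function(s) {
    cfg <- synthetic_config(n_genera = 1, pairs_per_genus = 1, trees_per_species = 15,
                            leaves_per_tree = 1, seed = s)
    d <- generate_trait_dataset(cfg)
    gen <- generate_env_table(d, NULL, seed = s)
    env <- gen$env
    env$climate_pc1 <- climate_pc1(env[, grep("^clim", names(env))])$scores
    adj <- residualize_traits(gen$traits, env)
    tapply(adj$adjusted, paste(adj$species, adj$trait), function(v) all(v == ""))
  }))
  expect_gt(mean(unchanged), 0.78)
  expect_lt(mean(unchanged), 0.95)
})

test_that("species below the tree threshold are skipped with a warning", {
  cfg <- synthetic_config(n_genera = 1, pairs_per_genus = 1, trees_per_species = 3,
                          leaves_per_tree = 1, seed = 6)
  tm <- tree_means(generate_trait_dataset(cfg))
  env <- make_env_for(tm, rnorm(length(unique(tm$tree))))
  expect_warning(adj <- residualize_traits(tm, env), "skipped")
  expect_equal(adj$value[order(adj$species, adj$trait, adj$tree)],
               tm$value[order(tm$species, tm$trait, tm$tree)])
})
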