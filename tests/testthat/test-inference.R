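make_profile_values <- function(widespread, endemic, genera = NULL) {
  k <- length(widespread)
  genera <- genera %||% sprintf("G%02d", seq_len(k))
  data.frame(species = c(sprintf("w%d", seq_len(k)), sprintf("e%d", seq_len(k))),
             pair = rep(sprintf("P%02d", seq_len(k)), 2),
             genus = rep(genera, 2),
             range_class = rep(c("widespread", "endemic"), each = k),
             value = c(widespread, endemic))
}

test_that("pair deltas are antisymmetric and recover injected CV gaps", {
  v <- make_profile_values(c(2, 3, 4), c(2, 1, 5))
  pd <- pair_deltas(v)
  expect_equal(pd$delta, c(0, 2, -1))
  swapped <- v
  swapped$range_class <- ifelse(v$range_class == "endemic", "widespread", "endemic")
  expect_equal(pair_deltas(swapped)$delta, -pd$delta)
  incomplete <- v[-1, ]
  expect_error(pair_deltas(incomplete), "P01")
  # generator ground truth: injected tree-level CV gap on a tree-level trait
  gap <- 0.10
  des <- traitrange:::design_table(synthetic_config(seed = 1))
  targets <- data.frame(species = des$species, trait = "WSG",
                        cv = ifelse(des$range_class == "widespread", 0.15 + gap, 0.15))
  cfg <- synthetic_config(trees_per_species = 50, leaves_per_tree = 1,
                          species_cv_targets = targets, seed = 10)
  prof <- species_variability_profile(generate_trait_dataset(cfg))
  v2 <- merge(prof$cv[prof$cv$trait == "WSG", ], prof$meta, by = "species")
  v2$value <- v2$cv_corrected
  pd2 <- pair_deltas(v2)
  se <- sd(pd2$delta) / sqrt(nrow(pd2))
  expect_lt(abs(mean(pd2$delta) - gap), 2 * se + 0.02)
})

test_that("paired intercept test handles degenerate inputs exactly", {
  res0 <- paired_intercept_test(rep(0, 6), sprintf("G%d", 1:6))
  expect_equal(res0$intercept, 0)
  expect_equal(res0$p_value, 1)
  resc <- paired_intercept_test(rep(0.3, 6), sprintf("G%d", 1:6))
  expect_equal(resc$intercept, 0.3)   # mean oracle
  expect_equal(resc$genus_variance, 0)
  expect_lt(resc$p_value, 1e-6)
  expect_error(paired_intercept_test(c(1, 2), c("a", "b")), "at least 3")
})

test_that("with one pair per genus the paired test equals the one-sample ML likelihood-ratio test", {
  set.seed(55)
  for (i in 1:50) {
    deltas <- rnorm(14, mean = 0.02, sd = 0.05)
    res <- paired_intercept_test(deltas, sprintf("G%02d", 1:14))
    n <- length(deltas)
    m <- mean(deltas)
    stat <- n * log(sum(deltas^2) / sum((deltas - m)^2))
    p_oracle <- pchisq(stat, 1, lower.tail = FALSE)
    expect_equal(res$p_value, p_oracle, tolerance = 1e-6)
    expect_equal(res$intercept, m, tolerance = 1e-6)
  }
})

test_that("the containment rule reproduces the design's denominator degrees of freedom", {
  # 34 species in 14 genera (3 genera of 4 species, 11 of 2): ddf = 34 - 2 - 13
  tab <- study_species_table()
  set.seed(1)
  mod <- range_prediction_model(tab$eoo_km2, rnorm(34, 0.15, 0.03), tab$genus)
  expect_identical(mod$df_den, 19L)
  expect_identical(mod$df_num, 1L)
})

test_that("a noiseless linear predictor is recovered exactly with p -> 0", {
  tab <- study_species_table()
  pred <- log10(tab$eoo_km2) * 0.05 + 0.1
  mod <- range_prediction_model(tab$eoo_km2, pred, tab$genus)
  expect_equal(mod$slope, 1 / 0.05, tolerance = 1e-6)
  expect_lt(mod$lrt_p, 1e-12)
  expect_error(range_prediction_model(tab$eoo_km2, rep(1, 34), tab$genus), "constant")
})

test_that("Mantel r, exact p, and invariances match independent oracles", {
  set.seed(3)
  pts <- matrix(rnorm(10), 5, 2)
  dg <- as.matrix(dist(pts))
  # identical matrices: perfect correlation, smallest attainable p
  res <- mantel_test(dg, dg, n_perm = 99, seed = 2)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 100)
  # exact enumeration equals the filtered-cartesian-product oracle
  tv <- rnorm(5)
  tr <- abs(outer(tv, tv, "-"))
  res_ex <- mantel_test(dg, tr, n_perm = "exact")
  perms <- oracle_all_perms(5)
  ut <- upper.tri(dg)
  r_all <- apply(perms, 1, function(p) cor(dg[ut], tr[p, p][ut]))
  r_obs <- cor(dg[ut], tr[ut])
  expect_identical(nrow(perms), 120L)
  expect_equal(res_ex$p, mean(r_all >= r_obs - 1e-12))
  expect_equal(res_ex$r, r_obs)
  # joint relabeling of both matrices leaves the exact p unchanged
  q <- c(3, 5, 1, 2, 4)
  res_rel <- mantel_test(dg[q, q], tr[q, q], n_perm = "exact")
  expect_equal(res_rel$p, res_ex$p)
  expect_equal(res_rel$r, res_ex$r)
  # statistic agrees with the vegan implementation
  veg <- vegan::mantel(as.dist(dg), as.dist(tr), permutations = 99)
  expect_equal(res_ex$r, unname(veg$statistic), tolerance = 1e-12)
  expect_error(mantel_test(dg[1:3, 1:3], tr[1:3, 1:3]), "size >= 4")
  expect_error(mantel_test(dg, matrix(0, 5, 5)), "constant")
})

test_that("Mantel summaries count the full species-by-trait grid", {
  grid <- expand.grid(species = sprintf("s%02d", 1:34),
                      trait = traitrange:::all_traits())
  grid$p <- 1
  s <- summarize_mantel(grid)
  expect_identical(s$n_total, 272L)
  expect_identical(s$n_significant, 0L)
  grid$p <- rep(c(0.01, 0.5), length.out = 272)
  expect_identical(summarize_mantel(grid)$n_significant, 136L)
})

test_that("paired-test power rises with the injected CV gap", {
  gaps <- c(0, 0.05, 0.10, 0.15)
  des <- traitrange:::design_table(synthetic_config(seed = 1))
  reject <- sapply(gaps, function(g) {
    mean(sapply(1:60, function(s) {
      targets <- data.frame(species = des$species, trait = "WSG",
                            cv = ifelse(des$range_class == "widespread",
                                        0.12 + g, 0.12))
      cfg <- synthetic_config(trees_per_species = 10, leaves_per_tree = 1,
                              species_cv_targets = targets, seed = 7000 + s)
      prof <- species_variability_profile(generate_trait_dataset(cfg))
      v <- merge(prof$cv[prof$cv$trait == "WSG", ], prof$meta, by = "species")
      v$value <- v$cv_corrected
      pd <- pair_deltas(v)
      paired_intercept_test(pd$delta, pd$genus)$p_value < 0.05
    }))
  })
  expect_true(all(diff(reject) >= -0.05))   # non-decreasing up to MC noise
  expect_lt(reject[1], 0.15)
  expect_gt(reject[4], reject[1])
})
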