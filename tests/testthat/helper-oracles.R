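# Independent brute-force oracles used across the test files.

# Mean pairwise Euclidean distance by explicit double loop.
oracle_mean_pairwise <- function(pts) {
  n <- nrow(pts); tot <- 0; cnt <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sqrt(sum((pts[i, ] - pts[j, ])^2)); cnt <- cnt + 1
  }
  tot / cnt
}

# Nearest-neighbour distances by explicit loop.
oracle_nn <- function(pts) {
  n <- nrow(pts)
  sapply(seq_len(n), function(i) {
    min(sapply(seq_len(n)[-i], function(j) sqrt(sum((pts[i, ] - pts[j, ])^2))))
  })
}

# Grid dedupe by explicit cell bucketing, lowest record id kept.
oracle_dedupe_ids <- function(x, y, ids, cell = 1) {
  key <- paste(floor(x / cell), floor(y / cell))
  unname(sapply(split(ids, key), function(v) sort(v)[1]))
}

# Method-of-moments expected-mean-squares solution for a balanced
# genus/species/tree/leaf nested design (a genera, b species per genus,
# c trees per species, n leaves per tree), on log values.
oracle_nested_anova <- function(d, a, b, cc, n) {
  y <- log(d$value)
  gm <- mean(y)
  mu_g <- tapply(y, d$genus, mean)
  mu_s <- tapply(y, d$species, mean)
  mu_t <- tapply(y, d$tree, mean)
  ss_a <- b * cc * n * sum((mu_g - gm)^2)
  ss_b <- cc * n * sum((mu_s - mu_g[substr(names(mu_s), 1, 3)])^2)
  tree_species <- tapply(d$species, d$tree, function(v) v[1])
  ss_c <- n * sum((mu_t - mu_s[tree_species[names(mu_t)]])^2)
  ss_e <- sum((y - mu_t[d$tree])^2)
  ms_a <- ss_a / (a - 1); ms_b <- ss_b / (a * (b - 1))
  ms_c <- ss_c / (a * b * (cc - 1)); ms_e <- ss_e / (a * b * cc * (n - 1))
  ve <- ms_e
  vc <- max(0, (ms_c - ms_e) / n)
  vb <- max(0, (ms_b - ms_c) / (cc * n))
  va <- max(0, (ms_a - ms_b) / (b * cc * n))
  comp <- c(genus = va, species = vb, tree = vc, leaf = ve)
  comp / sum(comp)
}

# All permutations of 1:n through a filtered cartesian product - an
# algorithm unrelated to the package's recursive generator.
oracle_all_perms <- function(n) {
  g <- do.call(expand.grid, rep(list(seq_len(n)), n))
  g <- g[apply(g, 1, function(r) length(unique(r)) == n), , drop = FALSE]
  as.matrix(unname(g))
}

# Small balanced synthetic dataset builder used by several files.
tiny_config <- function(seed = 1, trees = 4, leaves = 2, ...) {
  synthetic_config(n_genera = 3, pairs_per_genus = c(1, 1, 1),
                   trees_per_species = trees, leaves_per_tree = leaves,
                   seed = seed, ...)
}
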