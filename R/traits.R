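## Per-species trait variability statistics: coefficient of variation with a
## small-sample correction, functional dispersion (FDis) in PCA score space,
## and hierarchical variance decomposition across genus / species / tree /
## leaf levels.

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#' Traits are strictly positive, so a non-positive mean is an error.
#'
#' @param values numeric vector, length >= 2.
#' @return Dimensionless CV.
#' @export
cv <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) abort_validation("cv needs at least 2 values")
  m <- mean(values)
  if (!is.finite(m) || m <= 0) abort_validation("cv needs a positive mean")
  stats::sd(values) / m
}

#' Sample-size-corrected coefficient of variation
#'
#' `cv * (1 + 1/(4n))`: the standard normal-theory correction for the
#' downward small-sample bias of the CV.  Species differ in how many trees
#' could be sampled, so uncorrected CVs are not comparable across species;
#' the correction factor tends to 1 as n grows.  The formula is isolated
#' here so an alternative correction can be swapped in at a single site.
#'
#' @inheritParams cv
#' @return Dimensionless corrected CV (always >= the raw CV).
#' @export
corrected_cv <- function(values) {
  n <- length(values)
  cv(values) * cv_correction_factor(n)
}

cv_correction_factor <- function(n) 1 + 1 / (4 * n)

#' Principal component analysis of a trait matrix
#'
#' Z-scores each trait column and eigen-decomposes the correlation
#' structure.  LDMC and the N:P ratio are excluded by default because they
#' are arithmetic combinations of traits already in the matrix.  Keeps
#' `min(n_components, rank)` components.  Sign convention: within each
#' component the largest-magnitude loading is positive.
#'
#' @param mat numeric matrix or data frame, individuals x traits.
#' @param exclude trait columns to drop before the PCA.
#' @param n_components maximum number of components to keep (default 5).
#' @return Object of class `trait_pca`: `scores` (individuals x kept
#'   components), `loadings`, `explained` (variance fractions for the kept
#'   components), `explained_all`, `n_components`.
#' @export
trait_pca <- function(mat, exclude = c("LDMC", "NP"), n_components = 5L) {
  mat <- as.matrix(mat)
  keep <- setdiff(colnames(mat) %||% character(), exclude)
  if (length(keep)) mat <- mat[, keep, drop = FALSE]
  if (nrow(mat) < 2L) abort_validation("trait_pca needs at least 2 individuals")
  sds <- apply(mat, 2L, stats::sd)
  if (any(sds == 0 | !is.finite(sds)))
    abort_validation("zero-variance trait column: %s",
                     paste(colnames(mat)[sds == 0 | !is.finite(sds)], collapse = ", "))
  z <- scale(mat)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  rank <- sum(ev > max(ev) * 1e-10)
  k <- min(n_components, rank)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- apply(rot, 2L, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(rot, 2L, flip, `*`)
  scores <- z %*% rot
  structure(list(scores = scores, loadings = rot,
                 explained = ev[seq_len(k)] / sum(ev),
                 explained_all = ev / sum(ev),
                 n_components = k),
            class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  cat(sprintf("trait PCA: %d components kept, %.1f%% of variance\n",
              x$n_components, 100 * sum(x$explained)))
  invisible(x)
}

#' Functional dispersion (FDis) per species
#'
#' For each species, the centroid of its individuals in ordination-score
#' space and the mean Euclidean distance of the individuals to that
#' centroid.  Singleton species get FDis 0 with a warning.
#'
#' @param scores numeric matrix, individuals x ordination axes.
#' @param species character/factor vector of species labels per individual.
#' @return Named numeric vector of FDis values, one per species.
#' @export
functional_dispersion <- function(scores, species) {
  scores <- as.matrix(scores)
  if (nrow(scores) != length(species))
    abort_validation("scores and species labels differ in length")
  out <- vapply(split(seq_along(species), species), function(idx) {
    if (length(idx) == 1L) return(0)
    s <- scores[idx, , drop = FALSE]
    centroid <- colMeans(s)
    mean(sqrt(rowSums(sweep(s, 2L, centroid)^2)))
  }, numeric(1))
  if (any(table(species) == 1L))
    warning("singleton species present; their FDis is reported as 0")
  out
}

#' Hierarchical variance decomposition of one trait
#'
#' Log-transforms the trait and fits a nested random-intercept model
#' (genus / species-in-genus / tree-in-species) by REML; the residual level
#' is the leaf for leaf-level traits and the tree for tree-level traits.
#' Variance components are returned as proportions of their sum.
#'
#' @param dataset a tidy `trait_dataset` (see [generate_trait_dataset()] or
#'   [read_trait_csv()]).
#' @param trait trait name to decompose.
#' @return Object of class `variance_decomposition`: named proportions over
#'   `c(genus, species, tree, leaf)` (the residual level carries the residual
#'   variance; for tree-level traits the `leaf` entry is dropped), plus the
#'   raw variance components as attribute `components`.
#' @export
variance_decomposition <- function(dataset, trait) {
  d <- dataset[dataset$trait == trait, , drop = FALSE]
  if (!nrow(d)) abort_validation("trait '%s' not present in the dataset", trait)
  if (any(d$value <= 0)) abort_validation("trait values must be strictly positive")
  d$logv <- log(d$value)
  leaf_level <- trait %in% leaf_level_traits() && any(!is.na(d$leaf))
  d$genus <- factor(d$genus); d$species <- factor(d$species); d$tree <- factor(d$tree)
  form <- if (leaf_level)
    logv ~ 1 + (1 | genus) + (1 | species) + (1 | tree)
  else
    logv ~ 1 + (1 | genus) + (1 | species)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = d, REML = TRUE,
               control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore",
                                           calc.derivs = FALSE))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  comp <- stats::setNames(vc$vcov, vc$grp)
  if (leaf_level) {
    out <- c(genus = unname(comp["genus"]), species = unname(comp["species"]),
             tree = unname(comp["tree"]), leaf = unname(comp["Residual"]))
  } else {
    out <- c(genus = unname(comp["genus"]), species = unname(comp["species"]),
             tree = unname(comp["Residual"]))
  }
  out[is.na(out)] <- 0
  if (lme4::isSingular(fit))
    warning(sprintf("singular fit for trait %s: some variance components are zero", trait))
  props <- out / sum(out)
  structure(props, class = "variance_decomposition", trait = trait,
            components = out)
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("Variance decomposition for %s (log scale):\n", attr(x, "trait")))
  for (nm in names(x)) cat(sprintf("  %-8s %5.1f%%\n", nm, 100 * x[[nm]]))
  invisible(x)
}

#' Collapse a tidy trait dataset to one value per tree and trait
#'
#' Leaf-level traits are averaged over the leaves of each tree; tree-level
#' traits are passed through.  This is the observation level at which
#' species CVs, the PCA and FDis are computed by default (within-tree leaf
#' variation is treated separately by the variance decomposition).
#'
#' @param dataset a tidy `trait_dataset`.
#' @return Data frame with columns genus, species, pair, range_class, tree,
#'   trait, value.
#' @export
tree_means <- function(dataset) {
  agg <- stats::aggregate(value ~ genus + species + pair + range_class + tree + trait,
                          data = dataset, FUN = mean)
  agg[order(agg$species, agg$trait, agg$tree), , drop = FALSE]
}

#' Per-species variability profile: corrected CVs and FDis
#'
#' Computes, for every species, the raw and sample-size-corrected CV of each
#' trait and the functional dispersion over the first principal components
#' of the (z-scored) trait matrix, excluding LDMC and N:P from the ordination.
#'
#' @param dataset a tidy `trait_dataset`.
#' @param level `"tree"` (default; leaf traits averaged per tree first) or
#'   `"leaf"` (leaf-level values feed the CVs directly).
#' @param n_components maximum PCA components for FDis (default 5).
#' @return List of class `variability_profile`: `cv` (data frame species x
#'   trait with n, cv_raw, cv_corrected), `fdis` (named vector), `pca`
#'   (the [trait_pca()] object), and `meta` (species, genus, pair,
#'   range_class lookup).
#' @export
species_variability_profile <- function(dataset, level = c("tree", "leaf"),
                                        n_components = 5L) {
  level <- match.arg(level)
  tm <- tree_means(dataset)
  cv_input <- if (level == "tree") tm else
    dataset[, c("genus", "species", "pair", "range_class", "tree", "trait", "value")]
  cvs <- do.call(rbind, lapply(split(cv_input, list(cv_input$species, cv_input$trait),
                                     drop = TRUE), function(d) {
    data.frame(species = d$species[1L], trait = d$trait[1L], n = nrow(d),
               cv_raw = cv(d$value), cv_corrected = corrected_cv(d$value),
               stringsAsFactors = FALSE)
  }))
  rownames(cvs) <- NULL
  ## individual x trait matrix on tree means for the ordination
  wide <- stats::reshape(tm[, c("species", "tree", "trait", "value")],
                         idvar = c("species", "tree"), timevar = "trait",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  mat <- as.matrix(wide[, setdiff(names(wide), c("species", "tree")), drop = FALSE])
  pca <- trait_pca(mat, n_components = n_components)
  fdis <- functional_dispersion(pca$scores, wide$species)
  meta <- unique(dataset[, c("species", "genus", "pair", "range_class")])
  rownames(meta) <- NULL
  structure(list(cv = cvs, fdis = fdis, pca = pca, meta = meta, level = level),
            class = "variability_profile")
}

#' @export
print.variability_profile <- function(x, ...) {
  cat(sprintf("Variability profile: %d species, %d traits (%s level)\n",
              length(unique(x$cv$species)), length(unique(x$cv$trait)), x$level))
  cat(sprintf("  PCA: %d components, %.1f%% of variance; FDis range %.3g-%.3g\n",
              x$pca$n_components, 100 * sum(x$pca$explained),
              min(x$fdis), max(x$fdis)))
  invisible(x)
}
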