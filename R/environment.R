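## Characterization of the trees' growing sites (mesoclimate score, crown
## light exposure, slope), per-species environmental CVs, and the
## residualization of trait values against environment used for the back-up
## analysis.

#' First climate ordination axis, shifted to be non-negative
#'
#' Z-scores the climate variables, runs a PCA, and returns the axis-1 scores
#' shifted by the absolute value of their overall minimum so the smallest
#' score is exactly 0 (coefficients of variation require a positive scale;
#' note the caveat that the CV is not shift-invariant, see the package
#' vignette).  Sign convention: the largest-magnitude loading is positive.
#'
#' @param climate numeric matrix or data frame of climate variables (trees x
#'   variables), no missing values.
#' @return List with `scores` (shifted axis-1 scores, min exactly 0),
#'   `explained` (fraction of variance on axis 1), `loadings`, and `shift`.
#' @export
climate_pc1 <- function(climate) {
  climate <- as.matrix(climate)
  if (nrow(climate) < 2L) abort_validation("climate_pc1 needs at least 2 trees")
  if (anyNA(climate)) abort_validation("climate matrix contains missing values")
  sds <- apply(climate, 2L, stats::sd)
  if (any(sds == 0))
    abort_validation("zero-variance climate column: %s",
                     paste(colnames(climate)[sds == 0], collapse = ", "))
  z <- scale(climate)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  v1 <- pc$rotation[, 1L]
  if (v1[which.max(abs(v1))] < 0) v1 <- -v1
  raw <- drop(z %*% v1)
  shift <- abs(min(raw))
  scores <- raw + shift
  scores[which.min(raw)] <- 0   # exact, not just to rounding
  list(scores = scores, explained = ev[1L] / sum(ev), loadings = v1,
       shift = shift)
}

#' Per-species coefficients of variation of the environment
#'
#' Sample-size-corrected CVs (same correction as the traits) of the climate
#' score, slope, and crown-light index per species.  Variables that are
#' identically zero for a species have no defined CV and are returned as
#' `NA` with a warning rather than silently reported as 0.
#'
#' @param env data frame with columns `tree`, `species`, `climate_pc1`,
#'   `slope`, `light`.
#' @return Data frame: species, variable, n, cv_corrected.
#' @export
env_cv <- function(env) {
  need <- c("species", "climate_pc1", "slope", "light")
  miss <- setdiff(need, names(env))
  if (length(miss)) abort_validation("missing column(s): %s", paste(miss, collapse = ", "))
  vars <- c("climate_pc1", "slope", "light")
  out <- do.call(rbind, lapply(split(env, env$species), function(d) {
    if (nrow(d) < 2L) abort_validation("species '%s' has fewer than 2 trees", d$species[1L])
    vals <- vapply(vars, function(v) {
      x <- d[[v]]
      if (all(x == 0)) return(NA_real_)
      cv(x) * cv_correction_factor(length(x))
    }, numeric(1))
    data.frame(species = d$species[1L], variable = vars, n = nrow(d),
               cv_corrected = vals, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (anyNA(out$cv_corrected))
    warning("some environmental CVs are undefined (variable identically zero); reported as NA")
  out
}

#' Residualize trait values against environmental covariates
#'
#' Per species and trait (on tree-level values; leaf traits are averaged per
#' tree first): each of climate score, light and slope is screened in a
#' univariate linear regression; covariates with p < `screen_p` enter one
#' joint linear model, those with p < `keep_p` there are retained, and the
#' trait is replaced by the residuals of the retained-covariate model plus
#' the original trait mean (preserving the measurement scale exactly).
#' Traits with no retained covariate are returned unchanged.  Species with
#' fewer than `min_trees` trees are skipped with a warning.  Collinear
#' retained covariates (aliased in the joint fit) are dropped and noted.
#'
#' @param dataset a tidy `trait_dataset`.
#' @param env data frame with columns `tree`, `climate_pc1`, `light`, `slope`.
#' @param screen_p univariate screening threshold (default 0.1).
#' @param keep_p retention threshold in the joint model (default 0.05).
#' @param min_trees minimum trees per species (default 5).
#' @return Tree-level data frame (columns genus, species, pair, range_class,
#'   tree, trait, value) with an `adjusted` column naming the retained
#'   covariates (empty string when the trait was left untouched).
#' @export
residualize_traits <- function(dataset, env, screen_p = 0.1, keep_p = 0.05,
                               min_trees = 5L) {
  if (!all(c("tree", "climate_pc1", "light", "slope") %in% names(env)))
    abort_validation("env must contain tree, climate_pc1, light, slope")
  tm <- tree_means(dataset)
  covars <- c("climate_pc1", "light", "slope")
  skipped <- character()
  res <- do.call(rbind, lapply(split(tm, list(tm$species, tm$trait), drop = TRUE),
                               function(d) {
    d$adjusted <- ""
    i <- match(d$tree, env$tree)
    if (anyNA(i)) abort_validation("tree '%s' missing from env table", d$tree[which(is.na(i))[1L]])
    e <- env[i, covars, drop = FALSE]
    if (nrow(d) < min_trees) {
      skipped <<- c(skipped, d$species[1L])
      return(d)
    }
    ## univariate screening
    screened <- covars[vapply(covars, function(v) {
      if (stats::sd(e[[v]]) == 0) return(FALSE)
      fit <- stats::lm(d$value ~ e[[v]])
      stats::coef(summary(fit))[2L, 4L] < screen_p
    }, logical(1))]
    if (!length(screened)) return(d)
    ## joint model; aliased (collinear) covariates are dropped
    X <- e[, screened, drop = FALSE]
    joint <- stats::lm(d$value ~ ., data = X)
    cf <- stats::coef(joint)[-1L]
    aliased <- names(cf)[is.na(cf)]
    if (length(aliased))
      message("dropping collinear covariate(s): ", paste(aliased, collapse = ", "))
    sm <- stats::coef(summary(joint))
    pvals <- sm[-1L, 4L]
    retained <- screened[screened %in% rownames(sm)[-1L][pvals < keep_p]]
    if (!length(retained)) return(d)
    final <- stats::lm(d$value ~ ., data = e[, retained, drop = FALSE])
    d$value <- stats::residuals(final) + mean(d$value)
    d$adjusted <- paste(retained, collapse = ",")
    d
  }))
  rownames(res) <- NULL
  if (length(skipped))
    warning("skipped species with fewer than ", min_trees, " trees: ",
            paste(unique(skipped), collapse = ", "))
  res <- res[order(res$species, res$trait, res$tree), , drop = FALSE]
  rownames(res) <- NULL
  res
}
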