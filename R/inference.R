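## Hypothesis tests: paired congeneric mixed-model intercept tests,
## variability -> log range-size prediction models (with containment
## degrees of freedom), and Mantel tests of trait-distance vs geographic
## distance.

#' Per-pair differences of a variability metric
#'
#' delta = metric(widespread) - metric(endemic), per congeneric pair.
#'
#' @param values data frame with columns `species`, `pair`, `genus`,
#'   `range_class`, `value` (one row per species for a given metric).
#' @return Data frame with columns pair, genus, delta.
#' @export
pair_deltas <- function(values) {
  need <- c("species", "pair", "genus", "range_class", "value")
  miss <- setdiff(need, names(values))
  if (length(miss)) abort_validation("missing column(s): %s", paste(miss, collapse = ", "))
  out <- do.call(rbind, lapply(split(values, values$pair), function(d) {
    w <- d[d$range_class == "widespread", , drop = FALSE]
    e <- d[d$range_class == "endemic", , drop = FALSE]
    if (nrow(w) != 1L || nrow(e) != 1L)
      abort_validation("pair '%s' lacks a complete endemic/widespread couple", d$pair[1L])
    data.frame(pair = d$pair[1L], genus = d$genus[1L],
               delta = w$value - e$value, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

## ML likelihood-ratio statistic for nested Gaussian linear models from
## residual sums of squares; degenerate zero-residual fits handled exactly.
lrt_from_rss <- function(rss0, rss1, n) {
  if (rss1 <= 1e-300) return(if (rss0 <= 1e-300) 0 else Inf)
  max(0, n * log(rss0 / rss1))
}

ml_lmm_lrt <- function(full_formula, null_formula, data) {
  ## ML fits for the likelihood-ratio test of one fixed-effect term
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore",
                            check.conv.singular = lme4::.makeCC(action = "ignore",
                                                                tol = 1e-4),
                            calc.derivs = FALSE)
  full <- suppressMessages(suppressWarnings(
    lme4::lmer(full_formula, data = data, REML = FALSE, control = ctrl)))
  null <- suppressMessages(suppressWarnings(
    lme4::lmer(null_formula, data = data, REML = FALSE, control = ctrl)))
  stat <- max(0, 2 * (as.numeric(stats::logLik(full)) - as.numeric(stats::logLik(null))))
  list(statistic = stat, p = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Paired congeneric intercept test
#'
#' Fits `delta ~ 1 + (1 | genus)` by REML (genera contributing two pairs
#' share one random intercept) and tests the intercept against zero with a
#' likelihood-ratio test between the ML fits with and without the fixed
#' intercept.  When the genus variance is estimated at zero (singular fit)
#' the model reduces to the classical one-sample formulation, and the same
#' reduction is used as an explicit fallback when the mixed fit fails.
#'
#' @param deltas numeric vector of per-pair differences.
#' @param genus character/factor vector of genus ids, one per pair.
#' @param metric optional metric label carried through to printing.
#' @return Object of class `paired_comparison`: intercept, its standard
#'   error, genus random-intercept variance, LRT statistic, p-value,
#'   `fallback` flag, n pairs, deltas.
#' @export
paired_intercept_test <- function(deltas, genus, metric = "metric") {
  if (length(deltas) < 3L) abort_validation("need at least 3 pairs")
  if (length(genus) != length(deltas))
    abort_validation("deltas and genus ids differ in length")
  d <- data.frame(delta = as.numeric(deltas), genus = factor(genus))
  fallback <- FALSE
  fit <- tryCatch(suppressMessages(suppressWarnings(
    lme4::lmer(delta ~ 1 + (1 | genus), data = d, REML = TRUE,
               control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore",
                                           calc.derivs = FALSE)))),
    error = function(e) NULL)
  if (is.null(fit) || isTRUE(tryCatch(lme4::isSingular(fit, tol = 1e-6),
                                      error = function(e) TRUE)))
    fallback <- TRUE
  if (!fallback) {
    ok <- tryCatch(suppressWarnings({
      sm <- summary(fit)$coefficients
      intercept <- sm[1L, 1L]; se <- sm[1L, 2L]
      vc <- as.data.frame(lme4::VarCorr(fit))
      genus_var <- vc$vcov[vc$grp == "genus"]
      lrt <- ml_lmm_lrt(delta ~ 1 + (1 | genus), delta ~ 0 + (1 | genus), d)
      stopifnot(all(is.finite(c(sm))))
      TRUE
    }), error = function(e) FALSE)
    if (!ok) fallback <- TRUE
  }
  if (fallback) {
    ## one-sample reduction: ordinary ML likelihood-ratio test of the mean
    n <- nrow(d)
    intercept <- mean(d$delta); se <- stats::sd(d$delta) / sqrt(n)
    genus_var <- 0
    rss1 <- sum((d$delta - intercept)^2); rss0 <- sum(d$delta^2)
    stat <- lrt_from_rss(rss0, rss1, n)
    lrt <- list(statistic = stat,
                p = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
  }
  structure(list(metric = metric, n_pairs = length(deltas),
                 intercept = intercept, se = se, genus_variance = genus_var,
                 lrt_statistic = lrt$statistic, p_value = lrt$p,
                 fallback = fallback, deltas = d),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("Paired congeneric test (%s), %d pairs\n", x$metric, x$n_pairs))
  cat(sprintf("  widespread - endemic intercept: %.4g (SE %.4g)\n", x$intercept, x$se))
  cat(sprintf("  genus random-intercept variance: %.4g%s\n", x$genus_variance,
              if (x$fallback) " (one-sample reduction)" else ""))
  cat(sprintf("  LRT chi^2(1) = %.3f, p = %.4g\n", x$lrt_statistic, x$p_value))
  invisible(x)
}

#' Range-size prediction model
#'
#' Fits `log10(EOO) ~ predictor + (1 | genus)` by REML and reports the
#' slope, an F statistic on containment (between-within) denominator
#' degrees of freedom `n - n_fixed - (n_genera - 1)`, and a
#' likelihood-ratio p-value from ML fits with and without the predictor.
#'
#' @param eoo_km2 extent of occurrence per species (km^2), strictly positive.
#' @param predictor variability metric per species (CV or FDis).
#' @param genus genus id per species.
#' @param predictor_name label for printing.
#' @param log_base base of the range-size log transform (default 10).
#' @return Object of class `range_model`: slope, intercept, F statistic,
#'   numerator/denominator df, F p-value, LRT statistic and p-value, genus
#'   variance, `fallback` flag.
#' @export
range_prediction_model <- function(eoo_km2, predictor, genus,
                                   predictor_name = "predictor", log_base = 10) {
  if (any(eoo_km2 <= 0)) abort_validation("EOO values must be strictly positive")
  if (stats::sd(predictor) == 0) abort_validation("constant predictor")
  if (length(unique(genus)) < 2L) abort_validation("need at least 2 genera")
  d <- data.frame(y = log(eoo_km2, base = log_base),
                  x = as.numeric(predictor), genus = factor(genus))
  n <- nrow(d); g <- nlevels(d$genus)
  ddf <- n - 2L - (g - 1L)   # containment rule: 2 fixed parameters
  fallback <- FALSE
  fit <- tryCatch(suppressMessages(suppressWarnings(
    lme4::lmer(y ~ x + (1 | genus), data = d, REML = TRUE,
               control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore",
                                           calc.derivs = FALSE)))),
    error = function(e) NULL)
  if (is.null(fit) || isTRUE(tryCatch(lme4::isSingular(fit, tol = 1e-6),
                                      error = function(e) TRUE)))
    fallback <- TRUE
  if (!fallback) {
    ok <- tryCatch(suppressWarnings({
      sm <- summary(fit)$coefficients
      slope <- sm["x", 1L]; slope_se <- sm["x", 2L]; intercept <- sm[1L, 1L]
      vc <- as.data.frame(lme4::VarCorr(fit))
      genus_var <- vc$vcov[vc$grp == "genus"]
      lrt <- ml_lmm_lrt(y ~ x + (1 | genus), y ~ 1 + (1 | genus), d)
      stopifnot(all(is.finite(c(sm))))
      TRUE
    }), error = function(e) FALSE)
    if (!ok) fallback <- TRUE
  }
  if (fallback) {
    ols <- stats::lm(y ~ x, data = d)
    sm <- stats::coef(summary(ols))
    slope <- sm["x", 1L]; slope_se <- sm["x", 2L]; intercept <- sm[1L, 1L]
    genus_var <- 0
    rss1 <- sum(stats::residuals(ols)^2)
    rss0 <- sum(stats::residuals(stats::lm(y ~ 1, data = d))^2)
    stat <- lrt_from_rss(rss0, rss1, n)
    lrt <- list(statistic = stat,
                p = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
  }
  Fstat <- (slope / slope_se)^2
  structure(list(predictor = predictor_name, n = n, n_genera = g,
                 slope = slope, slope_se = slope_se, intercept = intercept,
                 F_statistic = Fstat, df_num = 1L, df_den = ddf,
                 F_p = stats::pf(Fstat, 1L, ddf, lower.tail = FALSE),
                 lrt_statistic = lrt$statistic, lrt_p = lrt$p,
                 genus_variance = genus_var, fallback = fallback,
                 log_base = log_base),
            class = "range_model")
}

#' @export
print.range_model <- function(x, ...) {
  cat(sprintf("Range-size model: log%g(EOO) ~ %s + (1 | genus), n = %d species, %d genera\n",
              x$log_base, x$predictor, x$n, x$n_genera))
  cat(sprintf("  slope = %.4g (SE %.4g); F(%d, %d) = %.3f, p = %.4g\n",
              x$slope, x$slope_se, x$df_num, x$df_den, x$F_statistic, x$F_p))
  cat(sprintf("  LRT chi^2(1) = %.3f, p = %.4g%s\n", x$lrt_statistic, x$lrt_p,
              if (x$fallback) " (ordinary least-squares reduction)" else ""))
  invisible(x)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    for (j in seq_len(nrow(sub))) {
      perm <- integer(n); perm[k] <- n
      perm[-k] <- sub[j, ]
      out[row, ] <- perm
      row <- row + 1L
    }
  }
  out
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper off-diagonal triangles, with a
#' one-sided (greater) permutation p-value under simultaneous row/column
#' permutation of the second matrix:
#' `p = (1 + #\{permuted r >= observed r\}) / (1 + n_perm)`.
#' With `n_perm = "exact"` all `n!` permutations are enumerated (n <= 8)
#' and `p` is the exact proportion of permutations (identity included) with
#' `r >= observed`.
#'
#' @param d_geo,d_trait square symmetric distance matrices (equal size >= 4,
#'   zero diagonal), e.g. geographic distances and `|t_i - t_j|`.
#' @param n_perm number of random permutations (default 999) or `"exact"`.
#' @param seed integer seed for the permutation stream.
#' @return Object of class `mantel_result`: `r`, `p`, `n_perm`, `exact`.
#' @export
mantel_test <- function(d_geo, d_trait, n_perm = 999, seed = 1) {
  d_geo <- as.matrix(d_geo); d_trait <- as.matrix(d_trait)
  n <- nrow(d_geo)
  if (n < 4L || any(dim(d_geo) != n) || any(dim(d_trait) != n))
    abort_validation("matrices must be square, equal size >= 4")
  if (max(abs(d_geo - t(d_geo))) > 1e-8 || max(abs(d_trait - t(d_trait))) > 1e-8)
    abort_validation("matrices must be symmetric")
  if (any(abs(diag(d_geo)) > 1e-12) || any(abs(diag(d_trait)) > 1e-12))
    abort_validation("matrices must have zero diagonal")
  ut <- upper.tri(d_geo)
  a <- d_geo[ut]
  if (stats::sd(a) == 0 || stats::sd(d_trait[ut]) == 0)
    abort_validation("constant distance matrix: Mantel r undefined")
  r_obs <- stats::cor(a, d_trait[ut])
  exact <- identical(n_perm, "exact")
  if (exact) {
    if (n > 8L) abort_validation("exact enumeration limited to n <= 8")
    perms <- all_permutations(n)
    r_perm <- vapply(seq_len(nrow(perms)), function(i) {
      p <- perms[i, ]
      stats::cor(a, d_trait[p, p][ut])
    }, numeric(1))
    pval <- mean(r_perm >= r_obs - 1e-12)
    n_perm <- nrow(perms)
  } else {
    n_perm <- check_count(n_perm, "n_perm")
    r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      stats::cor(a, d_trait[p, p][ut])
    }, numeric(1)))
    pval <- (1 + sum(r_perm >= r_obs - 1e-12)) / (1 + n_perm)
  }
  structure(list(r = r_obs, p = pval, n_perm = n_perm, exact = exact),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%s, %d permutations)\n",
              x$r, x$p, if (x$exact) "exact" else "one-sided greater", x$n_perm))
  invisible(x)
}

#' Count significant Mantel tests
#'
#' @param results data frame with a `p` column (one row per species x trait
#'   test) or a list of `mantel_result` objects.
#' @param alpha significance threshold (default 0.05).
#' @return List with `n_significant` and `n_total`.
#' @export
summarize_mantel <- function(results, alpha = 0.05) {
  p <- if (is.data.frame(results)) results$p
       else vapply(results, function(r) r$p, numeric(1))
  list(n_significant = sum(p < alpha), n_total = length(p))
}
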