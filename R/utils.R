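## Internal helpers: validation and seed-stream management.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_validation <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) < 1L || any(!is.finite(x)) || any(x < min) || any(x != floor(x)))
    abort_validation("'%s' must contain integers >= %d", name, min)
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    abort_validation("'%s' must be a single value in [0, 1]", name)
  as.numeric(x)
}

check_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0))
    abort_validation("'%s' must be finite and >= 0", name)
  as.numeric(x)
}

## All stochastic draws in the package descend from one user seed.  Each
## logical stream (traits, occurrences per species, environment, permutations)
## offsets the seed by a fixed prime multiple so that streams are reproducible
## independently of each other and stay inside the 32-bit integer range.
substream_seed <- function(seed, offset) {
  if (!is.finite(seed) || seed != floor(seed))
    abort_validation("'seed' must be an integer")
  as.integer((as.double(seed) + 999983 * as.double(offset)) %% 2147483629L)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Traits measured on every leaf vs once per tree (pooled sample or wood core).
leaf_level_traits <- function() c("LA", "LT", "SLA", "LDMC")
tree_level_traits <- function() c("WSG", "N", "P", "NP")
all_traits <- function() c(leaf_level_traits(), tree_level_traits())

trait_units <- function() {
  c(LA = "cm2", LT = "mm", SLA = "cm2/g", LDMC = "g/g",
    WSG = "g/cm3", N = "%", P = "%", NP = "dimensionless")
}
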