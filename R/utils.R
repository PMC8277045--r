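# Internal helpers shared across modules.

# Round half away from zero to `digits` decimals. Base round() rounds half to
# even; printed percentage tables in this package use conventional half-up.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Scalar assertion helpers ---------------------------------------------------

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE", name))
  }
  invisible(x)
}

# Derive a child RNG seed from a base seed and a stream index, staying inside
# the 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 1009) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
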