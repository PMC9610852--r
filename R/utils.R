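# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic child seed for stage `k` of a run seeded with `seed`.
# Kept below 2^31 - 1 so set.seed() accepts it.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 7919 * as.numeric(k)) %%
               (.Machine$integer.max - 1L)) + 1L
}

stop_if_not_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (x < lo || x > hi)
    stop(sprintf("'%s' = %g outside [%g, %g]", name, x, lo, hi), call. = FALSE)
  invisible(x)
}

# Truncated standard normal draw (elementwise, |z| <= 3).
rnorm_trunc3 <- function(n) pmax(pmin(rnorm(n), 3), -3)

`%||%` <- function(a, b) if (is.null(a)) b else a
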