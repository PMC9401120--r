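`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` with the RNG seeded at `seed`, restoring the caller's RNG state
# afterwards so seeded helpers do not perturb an enclosing simulation.
with_preserved_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# One root seed fans out into independent substreams (pool, animals, injections).
# Seeds are drawn below .Machine$integer.max so they remain valid R integers.
derive_seeds <- function(seed, n) {
  with_preserved_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_count <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x == floor(x))
}
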