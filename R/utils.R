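# internal helpers

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is left untouched. seed = NULL runs unseeded.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# derive a reproducible child seed (kept within 32-bit integer range)
child_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + 7919 * as.double(i)) %% 2147483587
}

`%||%` <- function(a, b) if (is.null(a)) b else a
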