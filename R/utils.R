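## Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
## .Random.seed is restored afterwards. With seed = NULL the expression
## simply runs in the ambient RNG stream.
run_seeded <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv()) else
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Derive a distinct 31-bit sub-seed from a base seed and a stream index
## (computed in double precision to avoid integer overflow).
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 2011 + 7919 * as.numeric(k)) %% 2147480000)
}
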