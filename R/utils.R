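# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Seeded entry points stay reproducible
# without clobbering the session RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Frobenius norm of a matrix (or of X - WH when all three are given).
fnorm <- function(A) sqrt(sum(A^2))

# Relative change used by the common solver stopping rule.
rel_change <- function(new, old) {
  if (old == 0) return(0)
  abs(new - old) / old
}
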