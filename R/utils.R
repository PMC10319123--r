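# Internal helpers shared across modules.

# Run `expr` under a fixed seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Gamma draw parameterized by mean and coefficient of variation.
# cv = 0 degenerates to the mean.
rgamma_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
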