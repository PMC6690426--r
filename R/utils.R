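# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state; a NULL seed leaves the current stream untouched.
with_rng <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Comparison tolerance for "permuted statistic at least as extreme as
# observed": counts floating-point ties as extreme (conservative).
stat_ge <- function(t_perm, t_obs) {
  t_perm >= t_obs - 1e-10 * max(1, abs(t_obs))
}

# Clopper-Pearson interval for x successes out of n trials.
clopper_pearson <- function(x, n, level = 0.95) {
  stopifnot(level > 0, level < 1, x >= 0, x <= n, n >= 1)
  alpha <- 1 - level
  low <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  high <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(low, high)
}

# Monte Carlo standard error of a proportion estimated from n draws.
mc_se <- function(p, n) sqrt(p * (1 - p) / n)
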