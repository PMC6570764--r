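# Run code with a temporarily seeded RNG, restoring global state afterwards.
# All stochastic entry points route through this so a user-visible seed
# argument never clobbers the session RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Symmetric-capable Dirichlet sampler via normalized gammas.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  # guard against all-zero draws under tiny alpha
  bad <- rowSums(x) == 0
  if (any(bad)) x[bad, ] <- stats::rgamma(sum(bad) * k, shape = 1)
  x / rowSums(x)
}

# row-normalize with clamping away from exact zero
.normalize_rows <- function(x, floor = 1e-12) {
  x[x < floor] <- floor
  x / rowSums(x)
}

.stopifnot_scalar <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x)) {
    stop(name, " must be a single number")
  }
}
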