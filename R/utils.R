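# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Every generator is a pure function of (config, seed) because of this.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_config("configuration error: '%s' must lie in [0, 1]", name)
  invisible(x)
}

# Negative-binomial draw parameterised by mean and overdispersion
# (var = mu + dispersion * mu^2); dispersion 0 degenerates to Poisson.
rcounts <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, lambda = mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}
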