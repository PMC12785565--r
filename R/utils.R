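# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# Restores (or removes) .Random.seed afterwards so simulation functions do
# not perturb the caller's RNG stream. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had_seed) old_seed <- get(".Random.seed", envir = env)
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive `n` child seeds (< 2^31) from one master seed, deterministically.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_if_not_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}

# Uniform-grid check with a tolerance proportional to the step.
is_uniform_grid <- function(t, tol = 1e-6) {
  if (length(t) < 2L) return(TRUE)
  dt <- diff(t)
  max(abs(dt - dt[1])) <= tol * max(dt[1], .Machine$double.eps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
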