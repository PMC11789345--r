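# Internal helpers shared across modules.

fib_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "fiberfa_error")))
}

fib_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded internals never
#' perturb user-level random streams.
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-cell substream: every cell's draws depend only on
# (master seed, cell counter), never on how many cells precede it.
cell_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647L) * 48271 + i) %% 2147483647L
}

is_count_like <- function(x, tol = 1e-8) {
  is.numeric(x) && all(x >= 0) && all(abs(x - round(x)) < tol)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    fib_stop("fiberfa_config_error", "'%s' must be a finite scalar", name)
}
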