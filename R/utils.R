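# Internal utilities: centralized unit conversion and an isolated,
# seedable RNG stream that never perturbs (and is never perturbed by)
# the caller's global random state.

mm_to_cm <- function(x) x / 10
cm_to_mm <- function(x) x * 10

# A small self-contained RNG stream. Draws run under a private
# .Random.seed which is saved/restored around every call, so package
# randomness is fully reproducible from its own seeds.
local_rng <- function(seed) {
  seed <- as.integer(seed %% .Machine$integer.max)
  state <- NULL
  draw <- function(fun, ...) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    if (is.null(state)) set.seed(seed) else
      assign(".Random.seed", state, envir = globalenv())
    out <- fun(...)
    state <<- get(".Random.seed", globalenv())
    out
  }
  list(
    norm = function(n, mean = 0, sd = 1) draw(stats::rnorm, n, mean, sd),
    unif = function(n, min = 0, max = 1) draw(stats::runif, n, min, max),
    int = function(n, max) draw(function(n, max) sample.int(max, n,
                                                            replace = TRUE),
                                n, max)
  )
}

# Deterministic child seed derivation, kept below 2^31.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 69069 + 12345 * k) %% 2147483647)
}
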