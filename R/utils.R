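# RNG plumbing: every stochastic routine takes an explicit integer seed and
# derives child seeds with a splittable integer hash, so one top-level seed
# reproduces a whole dataset/run without touching the caller's RNG state.

# Use a local RNG scope: saves the global .Random.seed and restores it when
# the caller invokes $restore() (typically via on.exit).
.localRNG <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  list(restore = function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
}

#' Derive a child seed
#'
#' Deterministic integer hash used to split one seed into independent
#' streams (per slide, per patch, per training run). Stays below 2^31.
#'
#' @param seed integer parent seed.
#' @param i integer stream index.
#' @return integer child seed in \code{[0, 2^31 - 58)}.
#' @export
childSeed <- function(seed, i) {
  # multiplicative hash in double precision; products stay below 2^53
  as.integer((as.numeric(seed) * 69069 + as.numeric(i) * 1013904223 + 17) %%
             2147483591)
}

# clamp helper
.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
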