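# Seeded random-number scoping.
#
# Every stochastic step in the package (synthetic cohorts, imposter
# sampling, fold assignment) draws from a `local_rng`, a private RNG
# stream that neither reads nor perturbs the caller's global RNG state.
# Derived seeds (for per-subject or per-task streams) are drawn from the
# parent stream and stay below 2^31.

#' Private seeded RNG stream
#'
#' @param seed integer seed.
#' @return A list of drawing functions (`sample_int`, `runif`, `rnorm`,
#'   `derive_seed`) backed by an isolated Mersenne-Twister state.
#' @keywords internal
#' @export
local_rng <- function(seed) {
  state <- NULL
  run <- function(f) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    if (is.null(state)) {
      set.seed(as.integer(seed) %% .Machine$integer.max)
    } else {
      assign(".Random.seed", state, envir = globalenv())
    }
    on.exit({
      state <<- get(".Random.seed", envir = globalenv())
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    f()
  }
  list(
    sample_int = function(n, size = n, replace = FALSE)
      run(function() sample.int(n, size, replace = replace)),
    runif = function(n, min = 0, max = 1)
      run(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1)
      run(function() stats::rnorm(n, mean, sd)),
    derive_seed = function()
      run(function() sample.int(.Machine$integer.max - 1L, 1L))
  )
}
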