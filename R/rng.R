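# Seeded RNG streams that leave the caller's .Random.seed untouched.
# Every stochastic operation in the package draws from one of these, so
# results are reproducible from an integer seed regardless of the session
# RNG state.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- NULL
  with_stream <- function(f) {
    g <- globalenv()
    old <- if (exists(".Random.seed", envir = g, inherits = FALSE))
      get(".Random.seed", envir = g) else NULL
    if (is.null(env$state)) {
      set.seed(as.integer(seed) %% .Machine$integer.max)
    } else {
      assign(".Random.seed", env$state, envir = g)
    }
    on.exit({
      env$state <- get(".Random.seed", envir = g)
      if (is.null(old)) {
        rm(".Random.seed", envir = g)
      } else {
        assign(".Random.seed", old, envir = g)
      }
    })
    f()
  }
  list(
    unif = function(n, min = 0, max = 1)
      with_stream(function() runif(n, min, max)),
    norm = function(n, mean = 0, sd = 1)
      with_stream(function() rnorm(n, mean, sd)),
    sample_int = function(n, size = n, replace = FALSE)
      with_stream(function() sample.int(n, size, replace = replace)),
    # derive a child integer seed (for C++ streams); kept below 2^31
    child = function(k = 1L)
      with_stream(function() as.integer(floor(runif(k) * 2147483399)) + 1L)
  )
}
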