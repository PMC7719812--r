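# Seeded RNG handles. Every generator in the package takes an explicit seed
# and draws through one of these, so the caller's .Random.seed is never
# consulted or modified.

local_rng <- function(seed) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("'seed' must be an integer")
  private <- new.env(parent = emptyenv())

  capture_global <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
  }
  restore_global <- function(state) {
    if (is.null(state)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", state, envir = globalenv())
    }
  }

  outer <- capture_global()
  set.seed(seed)
  private$state <- capture_global()
  restore_global(outer)

  run <- function(f, ...) {
    outer <- capture_global()
    restore_global(private$state)
    on.exit({
      private$state <- capture_global()
      restore_global(outer)
    })
    f(...)
  }

  list(
    sample  = function(x, size, replace = FALSE, prob = NULL)
      run(sample, x, size, replace = replace, prob = prob),
    rnorm   = function(n, mean = 0, sd = 1) run(stats::rnorm, n, mean, sd),
    runif   = function(n, min = 0, max = 1) run(stats::runif, n, min, max),
    rint    = function(n, max) run(function(n, max)
      sample.int(max, n, replace = TRUE), n, max),
    run     = run
  )
}

# Deterministic sub-seed derivation: master seed + stage label -> child seed.
# Keeps every derived seed in [1, 2^31 - 2].
derive_seed <- function(master, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag))) %% 1000003L
  val <- (as.double(master) * 48271 + as.double(h) * 16807) %% 2147483646
  as.integer(val) + 1L
}
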