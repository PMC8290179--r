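# Evaluate expr with a locally set RNG seed, restoring the caller's state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# One structured log line per stage, to stderr.
stageLog <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Derive a stream of child seeds from one parent seed, kept < 2^31.
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopIfNot3D <- function(a, what) {
  if (is.null(dim(a)) || length(dim(a)) != 3L)
    stop(what, " must be a 3D array", call. = FALSE)
}
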