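# Private RNG stream: when a seed is supplied, draws come from a stream
# seeded with it and the caller's .Random.seed is left untouched; with
# seed = NULL the global stream is used directly.
local_rng <- function(seed = NULL) {
  if (is.null(seed)) {
    return(list(
      sample = function(n, k) sample.int(n, k),
      int = function() sample.int(.Machine$integer.max - 1L, 1L),
      runif = function(n, min = 0, max = 1) stats::runif(n, min, max),
      draw = function(expr_fun) expr_fun()
    ))
  }
  state <- NULL
  with_state <- function(expr_fun) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (is.null(state)) set.seed(seed)
    else assign(".Random.seed", state, envir = globalenv())
    out <- expr_fun()
    state <<- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    out
  }
  list(
    sample = function(n, k) with_state(function() sample.int(n, k)),
    int = function() with_state(function() sample.int(.Machine$integer.max - 1L, 1L)),
    runif = function(n, min = 0, max = 1) with_state(function() stats::runif(n, min, max)),
    draw = function(expr_fun) with_state(expr_fun)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
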