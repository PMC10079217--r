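# Named random-number streams. One master seed per replicate expands into
# independent streams (init, food order, selection, mutation) so that
# toggling one stochastic component leaves the draws of the others unchanged.

#' Create named RNG streams from a master seed
#'
#' @param master_seed Integer master seed.
#' @param names Stream names.
#' @return An environment of class `"rng_streams"` holding one saved RNG
#'   state per stream.
#' @export
rng_streams <- function(master_seed,
                        names = c("init", "food", "selection", "mutation")) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1)
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)
  set.seed(as.integer(master_seed))
  seeds <- sample.int(.Machine$integer.max - 1L, length(names))
  env <- new.env(parent = emptyenv())
  env$states <- list()
  for (i in seq_along(names)) {
    set.seed(seeds[i])
    env$states[[names[i]]] <- .Random.seed
  }
  class(env) <- "rng_streams"
  env
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Evaluate an expression under a named stream
#'
#' Swaps the stream's saved RNG state in, evaluates `expr`, and saves the
#' advanced state back, leaving the global RNG state untouched.
#'
#' @param streams An [rng_streams()] object.
#' @param name Stream name.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_stream <- function(streams, name, expr) {
  if (is.null(streams$states[[name]])) {
    stop("unknown rng stream: ", name, call. = FALSE)
  }
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)
  set_rng_state(streams$states[[name]])
  value <- force(expr)
  streams$states[[name]] <- .Random.seed
  value
}
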