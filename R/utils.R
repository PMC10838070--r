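#' Set the RNG seed for the calling frame, restoring state on exit
#'
#' All seeded operations in the package use this helper so that a function's
#' randomness is fully determined by its `seed` argument and the caller's RNG
#' stream is left untouched.
#'
#' @noRd
local_seed <- function(seed, env = parent.frame()) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  # splice the saved state into the caller's exit handler by value
  do.call(on.exit,
          list(bquote(restore_rng_state(.(old))), add = TRUE),
          envir = env)
  set.seed(as.integer(seed %% .Machine$integer.max))
  invisible(seed)
}

#' @noRd
restore_rng_state <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    rm(".Random.seed", envir = globalenv())
  }
  invisible(NULL)
}
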