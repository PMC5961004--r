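# RNG scoping: save the caller's stream, seed a local one, restore after
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Derive a named substream seed from a root seed
#'
#' All pipeline randomness flows from one root seed fanned out per
#' stage through a stable hash of the stage name, so stages are
#' reproducible independently of execution order.
#'
#' @param root_seed integer root seed.
#' @param stream stage name.
#' @return integer seed below 2^31.
#' @export
substream_seed <- function(root_seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 2654435761) %% 1e9
  as.integer((as.numeric(root_seed) * 31 + h) %% 2147483647)
}
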