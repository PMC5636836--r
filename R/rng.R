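#' Derive independent substream seeds from one top-level seed
#'
#' All randomness in the package flows from a single integer seed. Named
#' substreams (e.g. \code{"predators"}, \code{"stomachs"}, \code{"simulation"})
#' are derived deterministically so that modules can be run and tested
#' independently while still reproducing jointly. The caller's RNG state is
#' left untouched.
#'
#' @param seed Integer top-level seed.
#' @param streams Character vector of substream names.
#' @return Named integer vector of seeds, one per stream.
#' @export
#' @examples
#' derive_seeds(1, c("predators", "stomachs"))
derive_seeds <- function(seed, streams) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.character(streams), length(streams) >= 1L)
  s <- with_preserved_rng({
    set.seed(as.integer(seed))
    sample.int(.Machine$integer.max - 1L, length(streams))
  })
  names(s) <- streams
  s
}

# Evaluate `code` without disturbing the caller's .Random.seed.
with_preserved_rng <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}
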