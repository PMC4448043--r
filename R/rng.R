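#' Counter-based per-photon random substreams
#'
#' Every photon history consumes deviates from its own substream, keyed by
#' the run seed and the photon index through a splitmix-style 64-bit hash.
#' The k-th deviate of a substream can be computed in O(1), which makes
#' photon histories reproducible, independent of execution order, and
#' replayable from R one deviate at a time - the scalar reference engine
#' uses exactly the deviates the compiled engine uses.
#'
#' @param seed run seed (integer-valued).
#' @param photon_index 1-based photon index.
#' @param from 0-based position of the first deviate to return.
#' @param n number of deviates.
#' @return Numeric vector of `n` deviates, each strictly inside (0, 1).
#' @examples
#' rng_substream(1, 1, 0, 5)
#' identical(rng_substream(1, 1, 0, 5), rng_substream(1, 1, 0, 5))
#' @export
rng_substream <- function(seed, photon_index, from = 0, n = 1) {
  stopifnot(length(seed) == 1L, length(photon_index) == 1L,
            photon_index >= 1, from >= 0, n >= 0)
  if (n == 0) return(numeric(0))
  .rng_substream(as.double(seed), as.double(photon_index - 1),
                 as.double(from), as.integer(n))
}

#' Sequential view of one photon's random substream
#'
#' Returns a closure-based stream object whose `$unif()` method yields the
#' photon's deviates in order, fetching them in blocks from the
#' counter-based generator.  `$position()` reports how many deviates have
#' been consumed.
#'
#' @inheritParams rng_substream
#' @param block block size used when fetching deviates.
#' @return List with functions `unif`, `position` and `reset`.
#' @examples
#' s <- photon_stream(seed = 1, photon_index = 1)
#' c(s$unif(), s$unif()) == rng_substream(1, 1, 0, 2)
#' @export
photon_stream <- function(seed, photon_index, block = 256L) {
  k <- 0
  buf <- numeric(0)
  buf_from <- 0
  list(
    unif = function() {
      i <- k - buf_from + 1
      if (i < 1 || i > length(buf)) {
        buf <<- rng_substream(seed, photon_index, from = k, n = block)
        buf_from <<- k
        i <- 1
      }
      k <<- k + 1
      buf[i]
    },
    position = function() k,
    reset = function() {
      k <<- 0
      buf <<- numeric(0)
      buf_from <<- 0
      invisible(NULL)
    })
}
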