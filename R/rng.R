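#' Named random-number substreams
#'
#' All stochastic operations in the package (simulation stages, control
#' sampling, reference-date assignment, review sampling) draw from a
#' substream derived deterministically from one global seed and a stream
#' name. Stages can therefore be re-run independently: changing the
#' matching draw does not perturb the simulator, and vice versa.
#'
#' @param seed Integer global seed.
#' @param stream Character stream name, e.g. `"match"`.
#' @return `substream_seed()`: an integer in `[0, 2^31)`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1, is.finite(seed), length(stream) == 1)
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% m
  as.integer((abs(as.numeric(seed)) %% m * 48271 + h) %% m)
}

#' @rdname substream_seed
#' @param code Expression evaluated with the substream seed in force; the
#'   caller's RNG state is restored afterwards.
#' @export
with_substream <- function(seed, stream, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stream))
  force(code)
}
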