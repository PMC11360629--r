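# Deterministic, component-scoped randomness.
#
# One user-facing integer seed drives a named stream per component (beat
# sequence, jitter, each noise kind, weight init, batching, ...) so that
# changing, say, the noise realisation never shifts the beat sequence.

#' Derive a component seed from a master seed and a stream name
#'
#' @param seed master integer seed
#' @param name character scalar naming the stream (e.g. `"beats"`, `"bw"`)
#' @return an integer in `[0, 2^31)` usable with [set.seed()]
#' @keywords internal
derive_seed <- function(seed, name) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_argument("`seed` must be a single non-missing number")
  }
  h <- 0
  for (b in utf8ToInt(name)) h <- (h * 131 + b) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 2654435761 + h) %% 2147483647)
}

# Run `expr` under a seeded RNG without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
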