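#' Deterministic random substreams
#'
#' Every random quantity in a simulation run is a pure function of the master
#' seed, a stream label, and the patient id. Results are therefore invariant
#' to patient iteration order and to chunked/parallel execution, and common
#' random numbers across scenarios come for free: two runs with the same seed
#' reuse identical uniforms wherever patient ids coincide.
#'
#' @param seed master integer seed.
#' @param stream character label of the random stream (e.g. `"dr_event"`).
#' @param ids positive integer patient ids.
#' @return numeric vector of uniforms, one per id, `substream_uniforms(s, l, i)`
#'   depending only on `(s, l, i)` elementwise.
#' @keywords internal
substream_uniforms <- function(seed, stream, ids) {
  stopifnot(length(ids) > 0L, all(ids >= 1L))
  u <- with_preserved_rng({
    set.seed(substream_seed(seed, stream))
    stats::runif(max(ids))
  })
  u[ids]
}

#' @rdname substream_uniforms
#' @keywords internal
substream_seed <- function(seed, stream) {
  b <- utf8ToInt(stream)
  h <- sum(b * seq_along(b) * 131) %% 1000003
  # keep derived seeds strictly below 2^31 (R integers are 32-bit)
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483629)
}

# Evaluate `code` with its own RNG state, restoring the caller's state after.
with_preserved_rng <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  code
}
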