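# Internal helpers shared across modules.

#' @keywords internal
clamp01 <- function(x) pmin(1, pmax(0, x))

# Derive a deterministic sub-seed (< 2^31) for a named random stream so that
# adding a new stream never perturbs draws of existing ones.
stream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 1000003L
  as.integer((as.numeric(seed) * 2654435.0 + h) %% 2147483647)
}

# Evaluate `expr` under the RNG state implied by (seed, stream), restoring the
# caller's RNG state afterwards.
with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, name))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 0-based half-open window index for 1-based positions
window_index <- function(pos, window) (pos - 1L) %/% window
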