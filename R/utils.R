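#' @keywords internal
"_PACKAGE"

# Deterministic 32-bit integer mixing for hierarchical RNG substreams.
# Each (seed, index...) tuple maps to its own substream seed, so that e.g.
# patient i's draws do not depend on how many patients precede it.
mix_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed %% 2147483647L)
  for (k in idx) {
    # splitmix-like affine step kept in double precision; all operands
    # stay below 2^53 so arithmetic is exact
    h <- (h * 69069 + as.double(k) * 12345 + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under its own RNG substream without disturbing the
# caller's RNG state.
with_substream <- function(seed, ..., expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(mix_seed(seed, ...))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(field, msg) {
  stop(sprintf("invalid parameter '%s': %s", field, msg), call. = FALSE)
}
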