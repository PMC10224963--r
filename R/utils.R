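# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x)

# derive a child seed from a base seed and a stream id, kept < 2^31
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 9973) %% 2147483647)
}
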