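#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed for a named random stream. All randomness in the
# package flows from one user seed; each component draws from its own stream
# so that components are individually re-generable.
sub_seed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483563
  as.integer((as.numeric(seed) %% 2147483563 * 1009 + h) %% 2147483563 + 1)
}

# Evaluate expr with a local RNG state seeded from a named stream.
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(sub_seed(seed, stream))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
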