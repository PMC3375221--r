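# Internal helpers shared across modules.

# Deterministic fan-out of one user-facing seed into per-stage substreams.
# Kept strictly below 2^31 so the result is always a valid R integer seed;
# arithmetic stays below 2^53 so it is exact in doubles.
deriveSeed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  s <- abs(as.double(seed)) %% 2147483647
  as.integer((s * 69069 + 2654435761 * (offset %% 997) + 1) %% 2147483647)
}

# set.seed without clobbering the caller's RNG state permanently
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
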