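# Small shared utilities.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval(expr, envir = parent.frame())
}

# Derive a child seed from a master seed and a stream index, staying within
# 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 16807) %% 2147483647)
}

# FNV-1a hash of an R object's serialization, as a hex string. Used to
# stamp output files with the configuration that produced them (no
# cryptographic strength needed or implied).
config_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 3)
  h <- 216613626
  for (b in as.integer(raw)) {
    h <- bitwXor(as.integer(h), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
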