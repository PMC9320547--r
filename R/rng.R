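# Seeded-stream helpers. Every generator draws from its own named stream so
# that adding a new generator never perturbs another's output, and the global
# RNG state of the calling session is left untouched.

#' Derive a sub-seed from a base seed and a stream label
#'
#' Deterministic, order-sensitive hash of the label folded into the base
#' seed. Result is always a valid 32-bit seed.
#'
#' @param seed integer base seed.
#' @param label character scalar naming the stream.
#' @return integer in [0, 2^31 - 2].
#' @keywords internal
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483646)
}

# Evaluate `expr` under `set.seed(seed)`, restoring the caller's RNG state.
with_rng <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(seed)
  expr
}
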