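# Deterministic seed derivation -------------------------------------------
#
# All randomness in the synthetic generator flows from one integer seed.
# Sub-streams (per limb, movement, trial, cycle, channel) use seeds derived
# by hashing the base seed together with string labels, so any subset of a
# session is reproducible in isolation without consuming a shared RNG stream.

# 31-bit multiplicative string hash (sdbm-style). The multiplier is kept
# small so h * 65599 + ch stays below 2^53 and every step is exact in double
# arithmetic.
hash31 <- function(x) {
  h <- 5381
  for (ch in utf8ToInt(x)) {
    h <- (h * 65599 + ch) %% 2147483647
  }
  h
}

#' Derive a reproducible sub-seed from a base seed and labels
#'
#' @param seed Base integer seed.
#' @param ... Labels (coerced to character) identifying the sub-stream, e.g.
#'   limb, movement, trial, cycle, channel.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  labs <- paste(c(as.character(as.integer(seed)), vapply(list(...), as.character, "")),
                collapse = "\x1f")
  as.integer(hash31(labs) %% 2147483645 + 1)
}

# Run an expression under a local, restored RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
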