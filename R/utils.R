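# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate code under a fixed seed without clobbering the caller's RNG state.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed for a pipeline stage; stays within 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483629L)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
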