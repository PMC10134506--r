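## Small shared helpers.

# Evaluate `code` under a temporary, seeded RNG state, restoring the
# caller's stream afterwards so seeded operations compose predictably.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  code
}

# Deterministic sub-seed derivation; keeps results < 2^31 so they are valid
# R integer seeds.
derive_seed <- function(seed, ...) {
  parts <- c(seed, vapply(list(...), function(x) {
    if (is.character(x)) sum(utf8ToInt(paste(x, collapse = ""))) else as.numeric(x)
  }, 0))
  h <- 0
  for (p in parts) h <- (h * 7919 + (abs(p) %% 2147483629) + 1) %% 2147483629
  as.integer(h)
}
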