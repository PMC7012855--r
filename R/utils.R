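# Run code under a fixed RNG seed, restoring the caller's RNG state after.
# All stochastic operations in the package route through this so generators
# are pure functions of (config, seed).
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}

# Deterministic per-stage child seed from a root seed (kept < 2^31).
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(index)) %%
               2147483587)
}
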