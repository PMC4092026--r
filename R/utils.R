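# Seed the RNG for the calling function without disturbing the caller's
# random state (restored when the calling frame exits).
local_rng <- function(seed, envir = parent.frame()) {
  withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible(NULL)
}

# Per-run seed derivation: deterministic, collision-free over a grid counter,
# kept inside 32-bit integer range.
derive_seed <- function(master_seed, counter) {
  as.integer((as.numeric(master_seed) * 100003 + counter) %% 2147483647L)
}
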