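# shared internal helpers

# Deterministic sub-seed derivation: one top-level seed per run, stage and
# chain seeds derived from it.  Values stay inside the 32-bit signed range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483647L)
}

stop_cfg <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
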