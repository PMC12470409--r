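# Structured error conditions so the CLI can map failures to exit codes:
# invalid-argument -> exit 2, data error -> exit 1.

stop_invalid <- function(msg, call. = FALSE) {
  stop(structure(
    class = c("ttafilter_invalid_argument", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_data <- function(msg, call. = FALSE) {
  stop(structure(
    class = c("ttafilter_data_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Run `expr` with a temporarily seeded RNG, restoring the caller's RNG state.
# All randomness in the package flows through this helper so that a single
# integer seed makes every artifact reproducible.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a sub-seed from a master seed by a fixed offset, kept inside the
# 32-bit integer range R requires.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1009 + offset) %% 2147483647)
}
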