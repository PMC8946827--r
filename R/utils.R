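# Run code with a locally seeded RNG, restoring the caller's RNG state.
# seed = NULL leaves the global stream untouched (caller-controlled).
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0) {
    stop("seed must be a single non-negative integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stream label, keeping the
# result in the 32-bit integer range.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 1009 + as.double(stream) * 7919) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
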