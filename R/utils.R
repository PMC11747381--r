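# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring the caller's RNG
#' state afterwards. Keeps generators and mock scorers pure functions of their
#' seed without clobbering the global stream.
#' @noRd
with_rng <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a per-step sub-seed from a base seed; mixes in the step index so each
# scorer call is independently reproducible. Kept below 2^31.
step_seed <- function(seed, step) {
  (as.double(seed) * 48271 + as.double(step) * 7919) %% 2147483647
}

# Byte-order (C locale) sort, independent of the session locale.
sort_c <- function(x) {
  if (length(x) == 0L) return(character())
  sort(x, method = "radix")
}

stopf <- function(fmt, ..., class = "gcdecode_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
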