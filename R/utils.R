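# Internal helpers shared across modules.

stopf <- function(fmt, ..., class = "metamerlab_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stopf("%s contains non-finite values", what,
                                class = "metamerlab_validation_error")
  invisible(x)
}

check_scalar_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("%s must be a single finite number", what,
          class = "metamerlab_validation_error")
  invisible(x)
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derive a distinct child seed from a parent seed (kept within 32-bit range).
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sem <- function(x) stats::sd(x) / sqrt(length(x))
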