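# Internal helpers shared across modules.

# Deterministic 32-bit sub-seed derivation: every source of randomness in the
# package draws from a seed derived from the user's master seed so that
# cohorts, restarts and splits are individually reproducible.
derive_seed <- function(seed, ...) {
  offsets <- c(...)
  x <- as.double(seed) %% 2147483647
  for (o in offsets) {
    x <- (x * 48271 + as.double(o) * 9973 + 1) %% 2147483647
  }
  as.integer(x)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (allow_inf || is.finite(x)) && x >= lower && x <= upper
  if (!ok) {
    abort(sprintf("`%s` must be a single number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) && is.finite(x) &&
    x >= min && x == round(x)
  if (!ok) abort(sprintf("`%s` must be an integer >= %d.", name, min))
  invisible(as.integer(x))
}

frob <- function(x) sqrt(sum(x^2))
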