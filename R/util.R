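# internal helpers shared across modules

# Deterministic per-iteration seed derived from (master seed, index...).
# Arithmetic kept in doubles (exact below 2^53), reduced mod 2^31 - 1 so the
# result is always a valid 32-bit seed. Changing the number of iterations
# never reshuffles earlier ones.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (k in seq_along(idx)) {
    s <- (s * 48271 + as.numeric(idx[k]) * 16807 + k) %% 2147483647
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_named <- function(...) stop(sprintf(...), call. = FALSE)

check_flag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_named("'%s' must be TRUE or FALSE", what)
  }
  x
}

check_number <- function(x, what, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_named("'%s' must be a single number", what)
  }
  if (x < lower || x > upper) {
    stop_named("'%s' must be in [%s, %s], got %s", what, lower, upper, x)
  }
  x
}

check_count <- function(x, what, lower = 0L) {
  check_number(x, what, lower = lower)
  if (x != as.integer(x)) stop_named("'%s' must be an integer", what)
  as.integer(x)
}
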