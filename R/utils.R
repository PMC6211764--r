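# Internal helpers shared across modules.

# Deterministic 31-bit seed derived from a master seed and a string key.
# All modular arithmetic stays below 2^53 so doubles are exact.
derive_seed <- function(seed, key) {
  m <- 2147483647
  h <- as.double(seed %% m)
  for (b in utf8ToInt(paste(key, collapse = "|"))) {
    h <- (h * 69069 + b) %% m
  }
  as.integer(h)
}

# round-half-up, used for mixture bookkeeping (round() would go half-even)
round_half_up <- function(x) floor(x + 0.5)

# warning with a stable machine-greppable code in brackets
warn_code <- function(code, fmt, ...) {
  warning(sprintf("[%s] %s", code, sprintf(fmt, ...)), call. = FALSE)
}

stop_input <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# per-row variance of a dense matrix without apply() overhead
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(0, nrow(x)))
  mu <- rowMeans(x)
  (rowSums(x^2) - n * mu^2) / (n - 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
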