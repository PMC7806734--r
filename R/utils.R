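# internal numerics shared across modules

# trapezoidal rule on a (possibly non-uniform) grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1L] + y[-n]) * diff(x)) / 2
}

# run code under a fixed RNG state without touching the caller's stream
local_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
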