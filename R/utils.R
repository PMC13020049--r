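# Internal helpers shared across modules.

# Derive a child stream seed from a master seed and an integer stream label.
# Keeps results < 2^31 so set.seed() accepts them.
derive_seed <- function(seed, stream) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(stream) * 1299721
  as.integer(s %% 2147483629)
}

# Min-max scale to [0, 1]; a constant vector maps to all zeros with a warning.
minmax_scale <- function(x, label = "feature") {
  rng <- range(x)
  if (!all(is.finite(rng))) stop(label, " contains non-finite values")
  if (rng[1] == rng[2]) {
    warning(label, " is constant; min-max scaling maps it to zeros")
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
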