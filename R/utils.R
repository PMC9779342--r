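# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# round half away from zero (base round() ties to even)
round_half_up <- function(x) floor(x + 0.5)

# deterministic 31-bit seed stream derived from a master seed plus integer tags,
# so every replicate / repeat draws from its own reproducible stream
derive_seed <- function(seed, ...) {
  s <- as.double(seed) %% 2147483647
  for (k in c(...)) {
    s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(s)
}

# one quantile convention repo-wide: linear interpolation between order
# statistics (type 7)
quantile7 <- function(x, probs) {
  unname(stats::quantile(x, probs = probs, type = 7, names = FALSE))
}

iqr7 <- function(x) {
  q <- quantile7(x, c(0.25, 0.75))
  q[2] - q[1]
}
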