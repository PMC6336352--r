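# Internal helpers.

# Round half away from zero (the convention that reproduces the published
# initial-mutant-count column; base round() is round-half-even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Central differences of y with respect to x on a possibly non-uniform grid;
# one-sided at the ends.
finite_diff <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 2L, length(y) == n)
  if (n == 2L) return(rep((y[2] - y[1]) / (x[2] - x[1]), 2L))
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  idx <- 2:(n - 1)
  g[idx] <- (y[idx + 1] - y[idx - 1]) / (x[idx + 1] - x[idx - 1])
  g
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_vector = FALSE) {
  if (!is.numeric(x) || (!allow_vector && length(x) != 1L) ||
      anyNA(x) || any(x < lower) || any(x > upper)) {
    abort(sprintf("`%s` must be %s in [%g, %g]",
                  name, if (allow_vector) "numeric" else "a single number",
                  lower, upper))
  }
  invisible(x)
}
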