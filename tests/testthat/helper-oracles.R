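# Independent oracles, deliberately avoiding the code paths they check.

# Characteristic polynomial coefficients via the Faddeev-LeVerrier recursion
# (matrix products and traces only — no eigendecomposition).  Returns
# c(c0, c1, ..., c_{n-1}, 1) for det(lambda*I - A).
char_poly_coefs <- function(a) {
  n <- nrow(a)
  coefs <- numeric(n + 1)
  coefs[n + 1] <- 1
  m <- diag(n)
  for (k in seq_len(n)) {
    am <- a %*% m
    ck <- -sum(diag(am)) / k
    coefs[n + 1 - k] <- ck
    m <- am + ck * diag(n)
  }
  coefs
}

# Largest real root of the characteristic polynomial, found by polyroot
# (Jenkins-Traub) — the oracle for the spectral radius of a symmetric matrix.
sr_oracle <- function(a) {
  roots <- polyroot(char_poly_coefs(a))
  max(Re(roots[abs(Im(roots)) < 1e-6]))
}

# Random symmetric non-negative matrix with zero diagonal.
random_nonneg_symmetric <- function(p, density = 1) {
  w <- matrix(runif(p * p), p, p)
  if (density < 1) w[matrix(runif(p * p) > density, p, p)] <- 0
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}
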