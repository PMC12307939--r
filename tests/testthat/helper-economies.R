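# Shared fixtures and independent oracles.

# Two-sector worked economy: identities hold by hand
# (10+20+70=100, 30+40+130=200, va = 100-40=60, 200-60=140).
e2 <- function(labels = c("s1", "s2")) {
  flow_table(Z = matrix(c(10, 30, 20, 40), 2, 2),
             x = c(100, 200), f = c(70, 130), va = c(60, 140),
             labels = labels)
}

# Random productive coefficient matrix: column sums capped below 1, which
# bounds the spectral radius for a nonnegative matrix.
random_productive_A <- function(n, cap = 0.85) {
  raw <- matrix(runif(n * n), n, n)
  sweep(raw, 2, colSums(raw) / runif(n, 0.1, cap), "/")
}

# Independent oracle for the Leontief inverse: truncated Neumann series
# sum_{k=0..K} A^k with K chosen so the remainder bound rho^(K+1)/(1-rho)
# falls below `remainder`.
neumann_inverse <- function(A, remainder = 1e-10) {
  rho <- max(Mod(eigen(A, only.values = TRUE)$values))
  stopifnot(rho < 1)
  K <- max(5, ceiling(log(remainder * (1 - rho)) / log(rho)))
  S <- diag(nrow(A))
  P <- diag(nrow(A))
  for (k in seq_len(K)) {
    P <- P %*% A
    S <- S + P
  }
  S
}
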