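# Internal helpers: classed errors and scoped RNG.

abort <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "bioecon_error")))
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Spectral radius of a square matrix
#'
#' Largest eigenvalue modulus; for a nonnegative technical-coefficient matrix
#' this is the quantity that must lie strictly below 1 for the economy to be
#' productive.
#'
#' @param M a square numeric matrix.
#' @return a single nonnegative number.
#' @export
spectral_radius <- function(M) {
  M <- as.matrix(M)
  stopifnot(nrow(M) == ncol(M))
  max(Mod(eigen(M, only.values = TRUE)$values))
}

#' Hawkins-Simon condition
#'
#' Checks that all leading principal minors of I - A are positive, the
#' classical necessary-and-sufficient condition for a nonnegative coefficient
#' matrix A to describe a productive economy (one able to meet any nonnegative
#' final demand with nonnegative gross outputs).
#'
#' @param A a square nonnegative matrix of technical coefficients (or a
#'   [coefficient_matrix()]).
#' @param tol positivity tolerance on each minor.
#' @return `TRUE` if every leading principal minor of `I - A` exceeds `tol`.
#' @export
hawkins_simon <- function(A, tol = 1e-12) {
  A <- coef_matrix_of(A)
  n <- nrow(A)
  B <- diag(n) - A
  for (k in seq_len(n)) {
    if (det(B[seq_len(k), seq_len(k), drop = FALSE]) <= tol) return(FALSE)
  }
  TRUE
}

# Accept either a bare matrix or a coefficient_matrix and return the matrix.
coef_matrix_of <- function(A) {
  if (inherits(A, "coefficient_matrix")) A$A else as.matrix(A)
}

# Relative mismatch |a - b| / max(1, |b|), used by accounting-identity checks.
rel_err <- function(a, b) abs(a - b) / pmax(1, abs(b))

fmt_musd <- function(x) formatC(x, format = "f", digits = 2)
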