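#' Technical coefficient matrix
#'
#' Wraps an n x n nonnegative matrix A of technical coefficients with its
#' sector labels. `A[i, j]` is the value of input from sector i required per
#' unit (dollar) of sector j's output -- columns are input recipes, the
#' standard orientation in which column sums are the base of output
#' multipliers.
#'
#' @param A square nonnegative numeric matrix.
#' @param labels sector names (defaults to dimnames of A).
#' @return object of class `coefficient_matrix` with fields `A`, `labels`.
#' @export
coefficient_matrix <- function(A, labels = NULL) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (ncol(A) != n) abort("A must be square", "bioecon_structural_error")
  if (any(A < 0)) abort("technical coefficients must be nonnegative",
                        "bioecon_structural_error")
  if (is.null(labels)) labels <- rownames(A)
  if (is.null(labels)) labels <- paste0("sector_", seq_len(n))
  if (length(labels) != n || anyDuplicated(labels)) {
    abort("labels must be n unique sector names", "bioecon_structural_error")
  }
  dimnames(A) <- list(labels, labels)
  structure(list(A = A, labels = as.character(labels)),
            class = "coefficient_matrix")
}

#' @export
print.coefficient_matrix <- function(x, ...) {
  cat(sprintf("<coefficient_matrix> %d sectors, spectral radius %.4f\n",
              length(x$labels), spectral_radius(x$A)))
  invisible(x)
}

#' Derive technical coefficients from a flow table
#'
#' Computes `A[i, j] = Z[i, j] / x[j]`: intermediate consumption of sector i's
#' product per unit of purchasing sector j's output.
#'
#' @param table a [flow_table()] with strictly positive total output.
#' @return a [coefficient_matrix()].
#' @export
compute_technical_coefficients <- function(table) {
  stopifnot(inherits(table, "flow_table"))
  zero <- which(table$x <= 0)
  if (length(zero)) {
    abort(sprintf("total output is zero (or negative) for sector(s): %s",
                  paste(table$labels[zero], collapse = ", ")),
          "bioecon_zero_output")
  }
  coefficient_matrix(sweep(table$Z, 2, table$x, "/"), table$labels)
}

#' Leontief inverse
#'
#' Computes `L = (I - A)^{-1}`, the total-requirements matrix: `L[i, j]` is
#' the gross output sector i must produce, directly and through all rounds of
#' intermediate purchases, per unit of final demand for sector j. Refuses to
#' invert a non-productive (or numerically singular) system.
#'
#' @param coeffs a [coefficient_matrix()] (or bare matrix).
#' @return object of class `leontief_inverse` with fields `L`, `labels`.
#' @export
leontief_inverse <- function(coeffs) {
  coeffs <- as_coefficient_matrix(coeffs)
  rho <- spectral_radius(coeffs$A)
  if (rho >= 1 - 1e-9) {
    abort(sprintf("economy is not productive: spectral radius of A is %.6f (must be < 1)",
                  rho), "bioecon_nonproductive")
  }
  n <- nrow(coeffs$A)
  L <- solve(diag(n) - coeffs$A)
  dimnames(L) <- list(coeffs$labels, coeffs$labels)
  structure(list(L = L, labels = coeffs$labels),
            class = "leontief_inverse")
}

as_coefficient_matrix <- function(x) {
  if (inherits(x, "coefficient_matrix")) x else coefficient_matrix(x)
}

#' @export
print.leontief_inverse <- function(x, ...) {
  cat(sprintf("<leontief_inverse> %d sectors, multipliers %.3f-%.3f\n",
              length(x$labels),
              min(colSums(x$L)), max(colSums(x$L))))
  invisible(x)
}

#' Final-demand shock vector
#'
#' A labeled vector of final-demand injections (million USD). Negative
#' entries are rejected unless `allow_negative = TRUE` (contractionary
#' scenarios).
#'
#' @param values numeric vector (optionally named) of injections.
#' @param labels sector names; defaults to `names(values)`.
#' @param allow_negative permit negative injections.
#' @return object of class `demand_shock` with fields `F`, `labels`.
#' @export
demand_shock <- function(values, labels = NULL, allow_negative = FALSE) {
  if (is.null(labels)) labels <- names(values)
  if (is.null(labels)) abort("demand shock needs sector labels",
                             "bioecon_structural_error")
  if (length(values) != length(labels)) {
    abort("values and labels differ in length", "bioecon_alignment_error")
  }
  if (!allow_negative && any(values < 0)) {
    abort("negative final-demand injections rejected (set allow_negative = TRUE)",
          "bioecon_structural_error")
  }
  structure(list(F = stats::setNames(as.numeric(values), labels),
                 labels = as.character(labels)),
            class = "demand_shock")
}

align_shock <- function(shock, labels) {
  if (!inherits(shock, "demand_shock")) shock <- demand_shock(shock)
  if (!identical(shock$labels, labels)) {
    if (setequal(shock$labels, labels)) {
      shock$F <- shock$F[labels]
      shock$labels <- labels
    } else {
      abort("shock sectors do not match the economy's sectors",
            "bioecon_alignment_error")
    }
  }
  shock
}

#' Total output impact of a final-demand injection
#'
#' The gross-output response `x = L %*% F` of every sector to the injection F,
#' in million USD.
#'
#' @param inverse a [leontief_inverse()].
#' @param shock a [demand_shock()] or named numeric vector.
#' @return named length-n numeric vector.
#' @export
total_output_impact <- function(inverse, shock) {
  stopifnot(inherits(inverse, "leontief_inverse"))
  shock <- align_shock(shock, inverse$labels)
  stats::setNames(as.numeric(inverse$L %*% shock$F), inverse$labels)
}

#' Output multipliers
#'
#' Column sums of the Leontief inverse: total economy-wide gross output
#' generated per unit of final demand delivered by each sector. Always >= 1;
#' equal to 1 exactly when a sector buys no intermediate inputs.
#'
#' @param inverse a [leontief_inverse()].
#' @return named length-n numeric vector (dimensionless).
#' @export
output_multipliers <- function(inverse) {
  stopifnot(inherits(inverse, "leontief_inverse"))
  colSums(inverse$L)
}

#' Decompose an impact into direct, indirect and induced components
#'
#' Splits the total gross-output impact of a final-demand injection into:
#' * **direct** -- the injection F itself;
#' * **indirect** -- the supply-chain ripple `(L_I - I) F` through
#'   intermediate purchases;
#' * **induced** -- the further ripple from household spending of labor
#'   income, `(L_II - L_I) F` restricted to the industry sectors; zero under
#'   the open (Type I) model.
#'
#' Type II closes the model with respect to households by augmenting A with a
#' consumption column (household purchases per unit of labor income) and a
#' labor-income row (income per unit of sector output), then inverting the
#' (n+1)-sector system.
#'
#' @param coeffs a [coefficient_matrix()].
#' @param shock a [demand_shock()] or named numeric vector.
#' @param closure `"type_I"` (default) or `"type_II"`.
#' @param household Type II closure data: list with `consumption` and `income`
#'   vectors in million USD (as stored on a [flow_table()]), plus the sector
#'   outputs `x` needed to convert them to coefficients; pass
#'   `household_coefficients()` output or a flow table's `household` with `x`.
#' @param x sector gross outputs (million USD), required for `"type_II"` to
#'   normalize the household row/column into coefficients.
#' @return object of class `impact_result`: data frame of per-sector `direct`,
#'   `indirect`, `induced`, `total` (million USD) and `share` (percent),
#'   with attribute `closure_type`.
#' @export
decompose_impacts <- function(coeffs, shock, closure = c("type_I", "type_II"),
                              household = NULL, x = NULL) {
  closure <- match.arg(closure)
  coeffs <- as_coefficient_matrix(coeffs)
  shock <- align_shock(shock, coeffs$labels)
  n <- length(coeffs$labels)

  L1 <- leontief_inverse(coeffs)$L
  direct <- shock$F
  indirect <- as.numeric((L1 - diag(n)) %*% shock$F)

  if (closure == "type_II") {
    if (is.null(household) || is.null(x)) {
      abort("type_II closure requires household consumption/income data and sector outputs x",
            "bioecon_missing_closure")
    }
    A2 <- augment_household(coeffs$A, household, x)
    rho <- spectral_radius(A2)
    if (rho >= 1 - 1e-9) {
      abort(sprintf("household-augmented system not productive (spectral radius %.6f)", rho),
            "bioecon_nonproductive")
    }
    L2 <- solve(diag(n + 1) - A2)
    induced <- as.numeric((L2[seq_len(n), seq_len(n)] - L1) %*% shock$F)
  } else {
    induced <- rep(0, n)
  }

  total <- direct + indirect + induced
  share <- if (sum(total) > 0) 100 * total / sum(total) else rep(NA_real_, n)
  res <- data.frame(sector = coeffs$labels, direct = direct,
                    indirect = indirect, induced = induced,
                    total = total, share = share, row.names = NULL)
  structure(res, closure_type = closure,
            class = c("impact_result", "data.frame"))
}

# Household endogenization: consumption column scaled per unit of household
# income, income row per unit of sector output.
augment_household <- function(A, household, x) {
  n <- nrow(A)
  inc <- as.numeric(household$income)
  cons <- as.numeric(household$consumption)
  if (length(inc) != n || length(cons) != n) {
    abort("household vectors must have one entry per sector",
          "bioecon_structural_error")
  }
  if (any(inc < 0) || any(cons < 0)) {
    abort("household coefficients must be nonnegative", "bioecon_structural_error")
  }
  total_income <- sum(inc)
  if (total_income <= 0) {
    abort("total household income must be positive for type_II closure",
          "bioecon_structural_error")
  }
  A2 <- rbind(cbind(A, cons / total_income), c(inc / x, 0))
  dimnames(A2) <- NULL
  A2
}

#' Percentage shares of named impacts
#'
#' Converts nonnegative named impact values to percentage shares of their
#' total. Shares sum to exactly 100 before any rounding.
#'
#' @param impacts named nonnegative numeric vector, at least one entry > 0.
#' @param digits optional rounding for the report layer (default: none).
#' @return named numeric vector of percentages.
#' @export
sector_shares <- function(impacts, digits = NULL) {
  if (any(impacts < 0)) {
    abort("impact values must be nonnegative", "bioecon_structural_error")
  }
  tot <- sum(impacts)
  if (tot <= 0) {
    abort("shares undefined: all impacts are zero", "bioecon_undefined_shares")
  }
  s <- 100 * impacts / tot
  if (!is.null(digits)) s <- round(s, digits)
  s
}
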