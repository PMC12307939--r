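#' Default sector labels for the synthetic economy
#'
#' A 27-sector nomenclature for a diversified middle-income productive
#' economy (primary production, manufacturing, utilities, services, R&D),
#' used when [generate_economy()] is called with `n = 27` and no labels.
#' For other n, generic `sector_k` labels are used unless supplied.
#'
#' @param n sector count.
#' @return character vector of n unique labels.
#' @export
default_sector_labels <- function(n) {
  full <- c("agriculture", "fishing", "forestry", "mining",
            "food_processing", "textiles", "wood_paper", "chemicals",
            "pharmaceuticals", "manufacturing", "energy", "water_waste",
            "construction", "trade", "transport", "hospitality",
            "information", "telecommunications", "finance", "real_estate",
            "professional_services", "R&D", "education", "health",
            "public_administration", "arts_recreation", "services")
  if (n == length(full)) full else paste0("sector_", seq_len(n))
}

#' Generate a synthetic balanced inter-industry economy
#'
#' Draws a random but exactly balanced flow table with the structure the
#' Leontief analysis assumes, standing in for a real supply-use-derived
#' industry-by-industry matrix. The recipe works backwards from the
#' coefficient matrix so that productivity is guaranteed by construction:
#'
#' 1. draw nonnegative coefficients and rescale each column of A so its sum
#'    is uniform on `[0.2, spectral_cap)` (column sums bound the spectral
#'    radius of a nonnegative matrix, so rho(A) < spectral_cap);
#' 2. draw positive final demands (log-normal, median ~400 MUSD per sector)
#'    and set gross output `x = (I - A)^{-1} f`, which is strictly positive
#'    because A is productive;
#' 3. set `Z = A %*% diag(x)` and recover `f = x - rowSums(Z)`,
#'    `va = x - colSums(Z)`, so both accounting identities hold exactly and
#'    value added is positive automatically (every column sum of A is below 1).
#'
#' Identical `(n, seed, spectral_cap, labels, household)` give bit-identical
#' tables; the caller's RNG stream is left untouched.
#'
#' @param n number of sectors (>= 1).
#' @param seed integer RNG seed.
#' @param spectral_cap strict upper bound, in (0, 1), on the spectral radius
#'   of the implied technical-coefficient matrix.
#' @param labels optional character vector of n unique sector names.
#' @param household if `TRUE`, also generate Type II closure data: a labor
#'   income row drawn as a share of each sector's value added, and a household
#'   consumption column proportional to a random basket scaled to total labor
#'   income.
#' @return a [flow_table()] passing [validate_economy()] with zero violations.
#' @export
generate_economy <- function(n, seed = 1L, spectral_cap = 0.9, labels = NULL,
                             household = FALSE) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    abort(sprintf("sector count n must be a positive integer (got %s)",
                  deparse(substitute(n))), "bioecon_invalid_size")
  }
  if (!is.numeric(spectral_cap) || spectral_cap <= 0 || spectral_cap >= 1) {
    abort(sprintf("spectral_cap must lie strictly inside (0, 1), got %g",
                  spectral_cap), "bioecon_invalid_parameter")
  }
  n <- as.integer(n)
  if (is.null(labels)) labels <- default_sector_labels(n)
  if (length(labels) != n || anyDuplicated(labels)) {
    abort("labels must be n unique sector names", "bioecon_invalid_parameter")
  }

  with_seed(seed, {
    # Column sums of A: uniform on [0.2, cap), falling back to [cap/2, cap)
    # when the cap itself is below 0.2.
    lo <- if (spectral_cap > 0.2) 0.2 else spectral_cap / 2
    raw <- matrix(stats::rgamma(n * n, shape = 0.8), n, n)
    colsum <- stats::runif(n, lo, spectral_cap)
    A <- sweep(raw, 2, colSums(raw) / colsum, "/")

    # Final demands drawn positive; gross output follows from the Leontief
    # system, so nonnegativity of f never needs rejection sampling.
    f0 <- stats::rlnorm(n, meanlog = log(400), sdlog = 0.6)
    x <- as.numeric(solve(diag(n) - A, f0))
    Z <- A %*% diag(x, n)
    f <- x - rowSums(Z)   # == f0 up to rounding; keeps the row identity exact
    va <- x - colSums(Z)

    hh <- NULL
    if (isTRUE(household)) {
      income <- va * stats::runif(n, 0.4, 0.7)       # labor share of value added
      basket <- stats::rgamma(n, shape = 1)
      # households spend 90% of labor income; keeps the augmented system productive
      consumption <- basket / sum(basket) * 0.9 * sum(income)
      hh <- list(consumption = consumption, income = income)
    }
    flow_table(Z = Z, x = x, f = f, va = va, labels = labels, household = hh)
  })
}
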