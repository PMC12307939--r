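#' Projection parameters
#'
#' A geometric annual benefit stream: the benefit accruing in year t is
#' `b * (1 + g)^(t - 1)` (year-end convention, t = 1..T), so cumulative
#' benefit to horizon T is the geometric partial sum. Two parameters are
#' exactly identified by two cumulative anchor totals, which is how printed
#' multi-horizon projections are reverse-engineered (see
#' [calibrate_projection()]).
#'
#' @param b initial annual benefit, million USD/year (>= 0).
#' @param g constant annual growth rate of the benefit (> -1; may be
#'   negative -- a decelerating stream).
#' @param horizons strictly positive integer horizons, ascending (default
#'   the reported 5/10/20-year set).
#' @return object of class `projection_params`.
#' @export
projection_params <- function(b, g = 0, horizons = c(5, 10, 20)) {
  if (b < 0) abort("initial annual benefit b must be nonnegative",
                   "bioecon_invalid_parameter")
  if (g <= -1) abort("growth g must exceed -1", "bioecon_invalid_parameter")
  if (length(horizons) == 0 || any(horizons <= 0) ||
      any(horizons != round(horizons)) || is.unsorted(horizons, strictly = TRUE)) {
    abort("horizons must be strictly positive integers in ascending order",
          "bioecon_invalid_horizon")
  }
  structure(list(b = b, g = g, horizons = as.integer(horizons)),
            class = "projection_params")
}

# Geometric partial sum S(T) = sum_{t=1..T} (1+g)^(t-1), stable near g = 0.
geom_sum <- function(g, T) {
  q <- 1 + g
  if (abs(g) < 1e-12) as.numeric(T) else (q^T - 1) / (q - 1)
}

#' Annual benefit stream implied by projection parameters
#'
#' @param params a [projection_params()].
#' @param T number of years.
#' @return length-T vector of year-by-year benefits (million USD).
#' @export
benefit_stream <- function(params, T) {
  stopifnot(inherits(params, "projection_params"))
  params$b * (1 + params$g)^(seq_len(T) - 1)
}

#' Cumulative benefits at each horizon
#'
#' `cumulative(T) = sum_{t=1..T} b (1+g)^(t-1)`; nondecreasing in T for
#' b >= 0 and exactly `b * T` when g = 0.
#'
#' @param params a [projection_params()].
#' @return named numeric vector, one entry per horizon (million USD).
#' @export
project_cumulative_benefits <- function(params) {
  stopifnot(inherits(params, "projection_params"))
  out <- vapply(params$horizons, function(T) params$b * geom_sum(params$g, T),
                numeric(1))
  stats::setNames(out, as.character(params$horizons))
}

#' Calibrate projection parameters to two cumulative anchors
#'
#' Given printed cumulative totals C1 at horizon T1 and C2 at T2 > T1,
#' recovers the unique (b, g) whose geometric stream reproduces both. The
#' growth rate solves the ratio equation
#' \deqn{S(T_2; g) / S(T_1; g) = C_2 / C_1, \qquad S(T;g)=\sum_{t=1}^{T}(1+g)^{t-1},}
#' whose left side is strictly increasing in g; it is bracketed on
#' `[-0.99, 1]` and solved by bisection to a 1e-12 bracket tolerance. Then
#' `b = C1 / S(T1; g)`. When `C2/C1` equals `T2/T1` exactly the g = 0 branch
#' is returned without iteration.
#'
#' @param anchors list of two `c(horizon, cumulative_total)` pairs, or a
#'   2x2 matrix/data frame with columns horizon, total.
#' @param horizons horizons for the returned [projection_params()].
#' @return a [projection_params()] reproducing both anchors to 1e-6 relative.
#' @export
calibrate_projection <- function(anchors, horizons = c(5, 10, 20)) {
  a <- do.call(rbind, lapply(anchors, as.numeric))
  if (!is.matrix(a) || nrow(a) != 2 || ncol(a) != 2) {
    abort("anchors must be two (horizon, cumulative_total) pairs",
          "bioecon_invalid_parameter")
  }
  a <- a[order(a[, 1]), , drop = FALSE]
  T1 <- a[1, 1]; C1 <- a[1, 2]
  T2 <- a[2, 1]; C2 <- a[2, 2]
  if (T1 == T2 || T1 <= 0 || any(c(T1, T2) != round(c(T1, T2)))) {
    abort("anchor horizons must be distinct positive integers",
          "bioecon_invalid_horizon")
  }
  if (C1 < 0 || C2 < C1) {
    abort(sprintf("infeasible anchors: cumulative totals cannot decrease (C(%d)=%g > C(%d)=%g)",
                  T1, C1, T2, C2), "bioecon_infeasible_anchors")
  }
  ratio <- C2 / C1
  if (ratio == T2 / T1) {
    return(projection_params(b = C1 / T1, g = 0, horizons = horizons))
  }
  fn <- function(g) geom_sum(g, T2) / geom_sum(g, T1) - ratio
  lo <- -0.99; hi <- 1
  # widen upward if the anchors imply growth above 100%/yr
  while (fn(hi) < 0 && hi < 1e3) hi <- hi * 2
  if (fn(lo) > 0 || fn(hi) < 0) {
    abort("anchors outside the calibratable growth range", "bioecon_infeasible_anchors")
  }
  g <- stats::uniroot(fn, c(lo, hi), tol = 1e-12)$root
  projection_params(b = C1 / geom_sum(g, T1), g = g, horizons = horizons)
}

#' Per-sector cumulative projections
#'
#' Projects each sector's geometric benefit stream and the cross-sector
#' totals, with per-horizon sector shares. Equal growth across sectors
#' preserves shares at every horizon; unequal growth shifts shares towards
#' the faster-growing sectors.
#'
#' @param initial named vector of initial annual benefits per sector.
#' @param growth named vector of per-sector growth rates, or one shared rate.
#' @param horizons positive integer horizons.
#' @return list with `cumulative` (sectors x horizons matrix, million USD),
#'   `totals` (per horizon), `shares` (sectors x horizons, percent).
#' @export
project_by_sector <- function(initial, growth, horizons = c(5, 10, 20)) {
  sectors <- names(initial)
  if (is.null(sectors)) abort("initial benefits must be named by sector",
                              "bioecon_alignment_error")
  if (length(growth) == 1 && is.null(names(growth))) {
    growth <- stats::setNames(rep(growth, length(initial)), sectors)
  }
  if (!setequal(names(growth), sectors)) {
    abort("growth map sectors do not match initial-benefit sectors",
          "bioecon_alignment_error")
  }
  growth <- growth[sectors]
  cum <- sapply(horizons, function(T) {
    mapply(function(b, g) b * geom_sum(g, T), initial, growth)
  })
  cum <- matrix(cum, nrow = length(sectors),
                dimnames = list(sectors, as.character(horizons)))
  totals <- colSums(cum)
  shares <- apply(cum, 2, sector_shares)
  list(cumulative = cum, totals = totals, shares = shares)
}
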