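#' Cash-flow series for cost-benefit appraisal
#'
#' Year-by-year benefit and cost streams over a T-year appraisal window with
#' an annual discount rate. The year-end convention is used throughout: the
#' first flow occurs one year out, so the discount factor in year t is
#' `(1 + r)^-t`, t = 1..T. (NPV figures shift by about one rate-unit if flows
#' are instead dated t = 0..T-1; the convention is fixed and documented here.)
#'
#' @param benefits length-T nonnegative benefit amounts (million USD).
#' @param costs length-T nonnegative cost amounts (million USD).
#' @param rate annual discount rate (fraction; default 0.05).
#' @return object of class `cash_flow_series`.
#' @export
cash_flow_series <- function(benefits, costs, rate = 0.05) {
  if (length(benefits) != length(costs)) {
    abort(sprintf("benefit and cost streams differ in length (%d vs %d)",
                  length(benefits), length(costs)), "bioecon_alignment_error")
  }
  if (length(benefits) < 1) {
    abort("streams must cover at least one year", "bioecon_invalid_parameter")
  }
  if (any(benefits < 0) || any(costs < 0)) {
    abort("benefit and cost amounts must be nonnegative", "bioecon_invalid_parameter")
  }
  if (rate <= -1) abort("discount rate must exceed -1", "bioecon_invalid_rate")
  structure(list(benefits = as.numeric(benefits), costs = as.numeric(costs),
                 rate = rate, T = length(benefits)),
            class = "cash_flow_series")
}

#' Present value of a stream
#'
#' `PV = sum_{t=1..T} amount_t / (1 + r)^t`. At r = 0 this is the plain sum.
#'
#' @param stream per-year amounts, first flow one year out.
#' @param rate annual discount rate (> -1).
#' @return present value (million USD).
#' @export
present_value <- function(stream, rate) {
  if (rate <= -1) abort("discount rate must exceed -1", "bioecon_invalid_rate")
  sum(stream / (1 + rate)^seq_along(stream))
}

#' Cost-benefit analysis of a cash-flow series
#'
#' Discounts both streams and reports the full metric set: undiscounted and
#' discounted totals, net present value `NPV = PV(benefits) - PV(costs)`, and
#' benefit-cost ratio `BCR = PV(benefits) / PV(costs)`. All values are kept
#' at full precision; rounding belongs to the report layer.
#'
#' @param flows a [cash_flow_series()].
#' @return object of class `cba_result` with fields `total_benefits`,
#'   `total_costs`, `pv_benefits`, `pv_costs`, `npv`, `bcr`, `rate`, `T`.
#' @export
cba <- function(flows) {
  stopifnot(inherits(flows, "cash_flow_series"))
  pvb <- present_value(flows$benefits, flows$rate)
  pvc <- present_value(flows$costs, flows$rate)
  structure(list(total_benefits = sum(flows$benefits),
                 total_costs = sum(flows$costs),
                 pv_benefits = pvb,
                 pv_costs = pvc,
                 npv = pvb - pvc,
                 bcr = if (pvc > 0) pvb / pvc else NA_real_,
                 rate = flows$rate, T = flows$T),
            class = "cba_result")
}

#' @export
print.cba_result <- function(x, ...) {
  cat(sprintf("<cba_result> %d-year appraisal at r = %.1f%%\n", x$T, 100 * x$rate))
  cat(sprintf("  PV benefits %s, PV costs %s, NPV %s MUSD, BCR %s\n",
              fmt_musd(x$pv_benefits), fmt_musd(x$pv_costs), fmt_musd(x$npv),
              if (is.na(x$bcr)) "undefined" else sprintf("%.2f", x$bcr)))
  invisible(x)
}

#' Net present value
#'
#' @param flows a [cash_flow_series()].
#' @return NPV in million USD (numeric scalar).
#' @export
npv <- function(flows) cba(flows)$npv

#' Benefit-cost ratio
#'
#' Discounted benefits over discounted costs. Invariant to scaling both
#' streams by a common factor, and invariant to the discount rate when the
#' two streams are proportional.
#'
#' @param flows a [cash_flow_series()].
#' @return dimensionless ratio.
#' @export
bcr <- function(flows) {
  res <- cba(flows)
  if (is.na(res$bcr)) {
    abort("benefit-cost ratio undefined: discounted costs are zero",
          "bioecon_undefined_ratio")
  }
  res$bcr
}

#' Default investment cost stream
#'
#' Spreads a lump investment evenly over the first `spread_years` years of a
#' T-year window, zero after; the stream sums to the investment exactly.
#'
#' @param investment_total million USD.
#' @param spread_years years over which the outlay is spread (1 = lump sum
#'   in year 1).
#' @param T appraisal horizon in years.
#' @return length-T cost stream.
#' @export
build_default_cost_stream <- function(investment_total, spread_years, T) {
  if (spread_years < 1 || spread_years != round(spread_years) || T < 1) {
    abort("spread_years and T must be positive integers", "bioecon_invalid_spread")
  }
  if (spread_years > T) {
    abort(sprintf("spread_years (%d) exceeds the appraisal horizon (%d)",
                  spread_years, T), "bioecon_invalid_spread")
  }
  c(rep(investment_total / spread_years, spread_years), rep(0, T - spread_years))
}
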