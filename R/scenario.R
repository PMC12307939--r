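#' Investment scenario
#'
#' Bundles the assumptions of a genomics-investment appraisal: the size of
#' the final-demand injection and its split across sectors, a productivity
#' improvement applied to target sectors, and optional strengthening of the
#' linkages from a source sector (R&D by default) to downstream sectors.
#' Defaults mirror the appraised case: a US$20M investment split equally
#' between R&D and agriculture, a 10% productivity improvement in
#' agriculture-related sectors, linkage strengthening available but off
#' (`linkage_delta = 0`) because no magnitude is established for it.
#'
#' @param investment_total injection size, million USD (default 20).
#' @param allocation named weights summing to 1 (default 0.5 R&D / 0.5
#'   agriculture).
#' @param productivity_gain fractional input-efficiency gain (default 0.10).
#' @param productivity_targets sectors receiving the gain (default
#'   agriculture-related: agriculture, fishing).
#' @param linkage_source sector whose sales coefficients are strengthened
#'   (default `"R&D"`).
#' @param linkage_targets purchasing sectors whose use of the source
#'   deepens (default education, fishing, agriculture).
#' @param linkage_delta additive increase to each affected coefficient
#'   (default 0 = off).
#' @return object of class `io_scenario`.
#' @export
scenario <- function(investment_total = 20,
                     allocation = c("R&D" = 0.5, "agriculture" = 0.5),
                     productivity_gain = 0.10,
                     productivity_targets = c("agriculture", "fishing"),
                     linkage_source = "R&D",
                     linkage_targets = c("education", "fishing", "agriculture"),
                     linkage_delta = 0) {
  if (investment_total < 0) {
    abort("investment_total must be nonnegative", "bioecon_invalid_parameter")
  }
  if (is.null(names(allocation)) || any(!nzchar(names(allocation)))) {
    abort("allocation must be a named vector of sector weights",
          "bioecon_invalid_parameter")
  }
  if (any(allocation < 0) || abs(sum(allocation) - 1) > 1e-9) {
    abort(sprintf("allocation weights must be nonnegative and sum to 1 (sum = %g)",
                  sum(allocation)), "bioecon_allocation_error")
  }
  if (productivity_gain <= -1) {
    abort("productivity_gain must exceed -1", "bioecon_invalid_parameter")
  }
  if (linkage_delta < 0) {
    abort("linkage_delta must be nonnegative", "bioecon_invalid_parameter")
  }
  structure(list(investment_total = investment_total,
                 allocation = allocation,
                 productivity_gain = productivity_gain,
                 productivity_targets = productivity_targets,
                 linkage_source = linkage_source,
                 linkage_targets = linkage_targets,
                 linkage_delta = linkage_delta),
            class = "io_scenario")
}

#' @export
print.io_scenario <- function(x, ...) {
  cat(sprintf("<io_scenario> %s MUSD into %s; productivity +%.0f%% on %s; linkage delta %g (%s -> %s)\n",
              fmt_musd(x$investment_total),
              paste(sprintf("%s (%.0f%%)", names(x$allocation), 100 * x$allocation),
                    collapse = ", "),
              100 * x$productivity_gain,
              paste(x$productivity_targets, collapse = ", "),
              x$linkage_delta, x$linkage_source,
              paste(x$linkage_targets, collapse = ", ")))
  invisible(x)
}

#' Read a scenario configuration file
#'
#' Accepts YAML or JSON with keys `investment_total`, `allocation`,
#' `productivity_gain`, `productivity_targets`, `linkage` (sub-keys `source`,
#' `targets`, `delta`), and optionally `closure`, `discount_rate`, `horizons`
#' (returned as attributes for the pipeline layer). Unknown keys are
#' rejected.
#'
#' @param path path to a `.yaml`/`.yml`/`.json` file.
#' @return an `io_scenario`; pipeline-level keys attached as attributes
#'   `closure`, `discount_rate`, `horizons` when present.
#' @export
read_scenario <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("investment_total", "allocation", "productivity_gain",
             "productivity_targets", "linkage", "closure", "discount_rate",
             "horizons")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    abort(paste0("unknown scenario key(s): ", paste(extra, collapse = ", ")),
          "bioecon_invalid_parameter")
  }
  base <- scenario()
  link <- cfg$linkage
  sc <- scenario(
    investment_total = cfg$investment_total %||% base$investment_total,
    allocation = if (!is.null(cfg$allocation)) unlist(cfg$allocation) else base$allocation,
    productivity_gain = cfg$productivity_gain %||% base$productivity_gain,
    productivity_targets = cfg$productivity_targets %||% base$productivity_targets,
    linkage_source = link$source %||% base$linkage_source,
    linkage_targets = link$targets %||% base$linkage_targets,
    linkage_delta = link$delta %||% base$linkage_delta)
  attr(sc, "closure") <- cfg$closure
  attr(sc, "discount_rate") <- cfg$discount_rate
  attr(sc, "horizons") <- cfg$horizons
  sc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the final-demand vector of a scenario
#'
#' Places `investment_total * weight` at each allocated sector and zero
#' elsewhere; the vector sums to `investment_total` exactly.
#'
#' @param scenario an [scenario()].
#' @param labels the economy's sector names.
#' @return a [demand_shock()].
#' @export
build_final_demand <- function(scenario, labels) {
  stopifnot(inherits(scenario, "io_scenario"))
  missing <- setdiff(names(scenario$allocation), labels)
  if (length(missing)) {
    abort(paste0("allocation names absent from the economy: ",
                 paste(missing, collapse = ", ")), "bioecon_label_error")
  }
  F <- stats::setNames(rep(0, length(labels)), labels)
  F[names(scenario$allocation)] <- scenario$investment_total * scenario$allocation
  demand_shock(F, labels)
}

#' Apply a productivity gain to target sectors
#'
#' A fractional productivity gain g in sector j means the same output is
#' produced from fewer intermediate inputs: column j of A is scaled by
#' `1 / (1 + g)`. Other columns are untouched. Input reduction can only keep
#' or lower the spectral radius, so the result stays productive.
#'
#' @param coeffs a [coefficient_matrix()].
#' @param targets sectors receiving the gain.
#' @param gain fraction > -1 (0.10 = 10% improvement).
#' @return a new [coefficient_matrix()].
#' @export
apply_productivity_gain <- function(coeffs, targets, gain) {
  coeffs <- as_coefficient_matrix(coeffs)
  if (gain <= -1) abort("gain must exceed -1", "bioecon_invalid_parameter")
  missing <- setdiff(targets, coeffs$labels)
  if (length(missing)) {
    abort(paste0("unknown target sector(s): ", paste(missing, collapse = ", ")),
          "bioecon_label_error")
  }
  if (gain == 0 || length(targets) == 0) return(coeffs)
  A <- coeffs$A
  j <- match(targets, coeffs$labels)
  A[, j] <- A[, j, drop = FALSE] / (1 + gain)
  coefficient_matrix(A, coeffs$labels)
}

#' Strengthen linkages from a source sector
#'
#' Adds `delta` to the coefficient `A[source, t]` for every target sector t:
#' each target's production recipe now draws more heavily on the source
#' sector (e.g. R&D services embedded in agriculture, fishing, education).
#' Rejected -- leaving the input unchanged -- if any affected column sum
#' reaches 1 or the matrix stops being productive.
#'
#' @param coeffs a [coefficient_matrix()].
#' @param source supplying sector whose linkages deepen.
#' @param targets purchasing sectors.
#' @param delta nonnegative coefficient increment.
#' @return a new [coefficient_matrix()].
#' @export
strengthen_linkages <- function(coeffs, source, targets, delta) {
  coeffs <- as_coefficient_matrix(coeffs)
  if (delta < 0) abort("delta must be nonnegative", "bioecon_invalid_parameter")
  missing <- setdiff(c(source, targets), coeffs$labels)
  if (length(missing)) {
    abort(paste0("unknown sector(s): ", paste(missing, collapse = ", ")),
          "bioecon_label_error")
  }
  if (delta == 0 || length(targets) == 0) return(coeffs)
  A <- coeffs$A
  i <- match(source, coeffs$labels)
  j <- match(targets, coeffs$labels)
  A[i, j] <- A[i, j] + delta
  bad <- colSums(A)[j] >= 1
  if (any(bad) || spectral_radius(A) >= 1 - 1e-9) {
    abort(sprintf("linkage delta %g makes the economy non-productive (affected column sums: %s)",
                  delta, paste(sprintf("%.3f", colSums(A)[j]), collapse = ", ")),
          "bioecon_nonproductive")
  }
  coefficient_matrix(A, coeffs$labels)
}

#' Run the base and adjusted cases of a scenario
#'
#' The base case evaluates the unmodified economy at the scenario's
#' final-demand injection; the adjusted case first applies the productivity
#' gain, then the linkage strengthening (fixed composition order), and
#' evaluates the same injection. Also returns the incremental impact
#' (adjusted minus base totals).
#'
#' @param table a valid [flow_table()].
#' @param scenario an [scenario()].
#' @param closure `"type_I"` or `"type_II"` (needs household data on `table`).
#' @return list with elements `base`, `adjusted` (both `impact_result`),
#'   `incremental` (named vector, million USD), and `shock`.
#' @export
run_base_and_adjusted <- function(table, scenario, closure = "type_I") {
  stopifnot(inherits(table, "flow_table"), inherits(scenario, "io_scenario"))
  A0 <- compute_technical_coefficients(table)
  shock <- build_final_demand(scenario, table$labels)
  A1 <- apply_productivity_gain(A0, scenario$productivity_targets,
                                scenario$productivity_gain)
  A1 <- strengthen_linkages(A1, scenario$linkage_source,
                            scenario$linkage_targets, scenario$linkage_delta)
  base <- decompose_impacts(A0, shock, closure,
                            household = table$household, x = table$x)
  adjusted <- decompose_impacts(A1, shock, closure,
                                household = table$household, x = table$x)
  list(base = base, adjusted = adjusted,
       incremental = stats::setNames(adjusted$total - base$total, table$labels),
       shock = shock)
}
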