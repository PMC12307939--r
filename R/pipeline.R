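#' Run the full appraisal pipeline
#'
#' One call from a flow table (supplied, read from CSV, or synthesized) and a
#' scenario to a complete report: base and adjusted sector impacts with
#' shares, multi-horizon cumulative benefit projections, and discounted
#' cost-benefit metrics. Stages run in fixed order -- economy, coefficients,
#' base/adjusted impacts, projection, CBA -- and any stage failure aborts
#' with the stage named; no partial report is produced.
#'
#' The projection is either given directly as [projection_params()] or
#' calibrated from two cumulative anchors via [calibrate_projection()]. The
#' CBA benefit stream is the projection's annual benefit stream over the
#' appraisal window; the cost stream spreads the scenario's investment via
#' [build_default_cost_stream()].
#'
#' @param table a [flow_table()], a path to a flow-table CSV, or `NULL` to
#'   synthesize one with [generate_economy()].
#' @param scen an [scenario()].
#' @param projection a [projection_params()], or a list of two
#'   `c(horizon, total)` anchor pairs.
#' @param cba_config list with `discount_rate` (default 0.05), `horizon`
#'   (years, default 10), `spread_years` (default = horizon).
#' @param closure `"type_I"` or `"type_II"`.
#' @param n,seed,spectral_cap synthesis parameters, used when `table` is NULL.
#' @param quiet suppress stage log messages (written to stderr).
#' @return object of class `pipeline_report` (a nested list; see
#'   [write_report()] and [render_summary()]).
#' @export
run_pipeline <- function(table = NULL,
                         scen = scenario(),
                         projection = list(c(5, 35), c(20, 79)),
                         cba_config = list(),
                         closure = "type_I",
                         n = 27, seed = 1L, spectral_cap = 0.9,
                         quiet = FALSE) {
  log_stage <- function(...) if (!quiet) message("[bioecon] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, bioecon_error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            "bioecon_stage_error", stage = name)
    })
  }

  cfg <- list(discount_rate = cba_config$discount_rate %||% 0.05,
              horizon = cba_config$horizon %||% 10L,
              spread_years = cba_config$spread_years %||% cba_config$horizon %||% 10L)

  tbl <- stage("economy", {
    if (is.null(table)) {
      log_stage("synthesizing %d-sector economy (seed %d, spectral cap %.2f)",
                n, seed, spectral_cap)
      generate_economy(n, seed = seed, spectral_cap = spectral_cap,
                       household = identical(closure, "type_II"))
    } else if (is.character(table)) {
      log_stage("reading flow table from %s", table)
      read_flow_table(table)
    } else table
  })
  stage("economy", {
    viol <- validate_economy(tbl)
    if (nrow(viol)) {
      abort(sprintf("flow table fails validation (%d violation(s), first: %s at %s)",
                    nrow(viol), viol$rule[1], viol$sector[1]),
            "bioecon_structural_error")
    }
  })

  log_stage("scenario: %s MUSD into %s; gain %.0f%%; linkage delta %g",
            fmt_musd(scen$investment_total),
            paste(names(scen$allocation), collapse = "+"),
            100 * scen$productivity_gain, scen$linkage_delta)
  impacts <- stage("impacts", run_base_and_adjusted(tbl, scen, closure))

  params <- stage("projection", {
    if (inherits(projection, "projection_params")) projection
    else calibrate_projection(projection)
  })
  horizon_totals <- project_cumulative_benefits(params)
  log_stage("projection: b = %.3f MUSD/yr, g = %.2f%%/yr", params$b, 100 * params$g)

  cba_res <- stage("cba", {
    flows <- cash_flow_series(
      benefits = benefit_stream(params, cfg$horizon),
      costs = build_default_cost_stream(scen$investment_total,
                                        cfg$spread_years, cfg$horizon),
      rate = cfg$discount_rate)
    cba(flows)
  })
  log_stage("cba: NPV %s MUSD, BCR %.2f over %d years at %.1f%%",
            fmt_musd(cba_res$npv), cba_res$bcr, cfg$horizon,
            100 * cfg$discount_rate)

  config <- list(scenario = unclass(scen), cba = cfg, closure = closure,
                 projection_params = list(b = params$b, g = params$g,
                                          horizons = params$horizons),
                 synthesis = if (is.null(table)) list(n = n, seed = seed,
                                                      spectral_cap = spectral_cap))
  report <- list(
    provenance = list(
      package = "bioecon",
      version = as.character(utils::packageVersion("bioecon")),
      table_source = if (is.null(table)) "synthetic"
                     else if (is.character(table)) table else "supplied",
      seed = if (is.null(table)) seed,
      config = config,
      config_hash = config_hash(config)),
    impacts = list(
      base = as.list(impacts$base),
      adjusted = as.list(impacts$adjusted),
      incremental = as.numeric(impacts$incremental),
      labels = tbl$labels,
      closure_type = closure),
    projections = list(
      b = params$b, g = params$g,
      horizons = as.integer(params$horizons),
      cumulative_totals = as.numeric(horizon_totals)),
    cba = unclass(cba_res),
    rounding = list(musd_digits = 2L, share_digits = 0L))
  structure(report, class = "pipeline_report")
}

# Stable content hash of the configuration: md5 of its canonical deparse.
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config, control = "all"), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a pipeline report as JSON
#'
#' Full precision (no rounding); regeneration from identical inputs is
#' byte-identical.
#'
#' @param report a `pipeline_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Render a human-readable summary of a pipeline report
#'
#' Fixed row order: total cost, discounted cost, total benefit, discounted
#' benefit, NPV, BCR; then sector shares of the adjusted impact; then
#' cumulative horizon totals. Money is rounded to 2 decimals and shares to
#' the nearest percent -- only here, at render time.
#'
#' @param report a `pipeline_report`.
#' @return character vector of lines (also usable via `cat(..., sep = "\n")`).
#' @export
render_summary <- function(report) {
  stopifnot(inherits(report, "pipeline_report"))
  for (sec in c("impacts", "projections", "cba")) {
    if (is.null(report[[sec]]) || length(report[[sec]]) == 0) {
      abort(sprintf("report is missing its '%s' section", sec),
            "bioecon_missing_section")
    }
  }
  cb <- report$cba
  lines <- c(
    sprintf("Total Cost: %s", fmt_musd(cb$total_costs)),
    sprintf("Discounted Cost: %s", fmt_musd(cb$pv_costs)),
    sprintf("Total Benefit: %s", fmt_musd(cb$total_benefits)),
    sprintf("Discounted Benefit: %s", fmt_musd(cb$pv_benefits)),
    sprintf("NPV: %s", fmt_musd(cb$npv)),
    sprintf("BCR: %.2f", cb$bcr))
  shares <- report$impacts$adjusted$share
  lab <- report$impacts$labels
  nz <- which(!is.na(shares) & shares >= 0.5)
  ord <- nz[order(shares[nz], decreasing = TRUE)]
  lines <- c(lines, "Sector shares (adjusted impact):",
             sprintf("  %s: %d%%", lab[ord], round(shares[ord])))
  lines <- c(lines, "Cumulative benefits by horizon:",
             sprintf("  %d years: %s", report$projections$horizons,
                     fmt_musd(report$projections$cumulative_totals)))
  lines
}

#' Structurally validate a pipeline report
#'
#' Checks a report (or a parsed report JSON) against the schema shipped at
#' `system.file("schema", "report_schema.json", package = "bioecon")`:
#' required sections and fields present with the expected JSON types.
#'
#' @param report a `pipeline_report` or a list parsed from report JSON.
#' @return character vector of problems; `character(0)` when valid.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(system.file("schema", "report_schema.json",
                                            package = "bioecon"))
  problems <- character()
  check <- function(obj, spec, where) {
    for (key in names(spec$properties)) {
      sub <- spec$properties[[key]]
      if (key %in% (unlist(spec$required) %||% character())) {
        if (is.null(obj[[key]])) {
          problems <<- c(problems, sprintf("missing required field %s.%s", where, key))
          next
        }
      }
      if (is.null(obj[[key]])) next
      type <- sub$type
      val <- obj[[key]]
      ok <- switch(type,
                   object = is.list(val) && (is.null(names(val)) == FALSE || length(val) == 0),
                   array = is.numeric(val) || is.character(val) || is.list(val),
                   number = is.numeric(val) && length(val) == 1,
                   integer = is.numeric(val) && length(val) == 1,
                   string = is.character(val) && length(val) == 1,
                   TRUE)
      if (!ok) {
        problems <<- c(problems, sprintf("field %s.%s is not of type %s", where, key, type))
      } else if (identical(type, "object") && !is.null(sub$properties)) {
        check(val, sub, paste0(where, ".", key))
      }
    }
  }
  check(unclass(report), schema, "report")
  problems
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(render_summary(x), sep = "\n")
  invisible(x)
}
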