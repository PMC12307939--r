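#' Inter-industry flow table
#'
#' The central data container: a square inter-industry transaction matrix
#' together with the sector accounts that close it. Entry `Z[i, j]` is the
#' value of sector i's sales to sector j (million USD per year); `x` is gross
#' output, `f` final demand, `va` value added. A valid table satisfies the two
#' national-accounting identities
#' \deqn{x_i = \sum_j Z_{ij} + f_i \quad (rows: sales side)}
#' \deqn{x_j = \sum_i Z_{ij} + va_j \quad (columns: cost side)}
#'
#' @param Z n x n nonnegative matrix of inter-industry flows (million USD).
#' @param x length-n vector of total (gross) output per sector.
#' @param f length-n vector of final demand per sector.
#' @param va length-n vector of value added per sector.
#' @param labels character vector of n unique sector names.
#' @param household optional list with elements `consumption` (length-n column
#'   of household purchases from each sector) and `income` (length-n row of
#'   labor income paid by each sector), enabling Type II closure.
#' @return an object of class `flow_table`.
#' @seealso [validate_economy()], [generate_economy()], [read_flow_table()]
#' @export
flow_table <- function(Z, x, f, va, labels = NULL, household = NULL) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (ncol(Z) != n) {
    abort("flow matrix Z must be square", "bioecon_structural_error")
  }
  if (is.null(labels)) labels <- paste0("sector_", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n || length(x) != n || length(f) != n || length(va) != n) {
    abort(sprintf("inconsistent dimensions: n = %d but labels/x/f/va have lengths %d/%d/%d/%d",
                  n, length(labels), length(x), length(f), length(va)),
          "bioecon_structural_error")
  }
  if (anyDuplicated(labels)) {
    abort("sector labels must be unique", "bioecon_structural_error")
  }
  if (!is.null(household)) {
    if (!is.list(household) ||
        length(household$consumption) != n || length(household$income) != n) {
      abort("household closure data must supply length-n consumption and income vectors",
            "bioecon_structural_error")
    }
    household <- list(consumption = as.numeric(household$consumption),
                      income = as.numeric(household$income))
  }
  dimnames(Z) <- list(labels, labels)
  structure(list(Z = Z,
                 x = stats::setNames(as.numeric(x), labels),
                 f = stats::setNames(as.numeric(f), labels),
                 va = stats::setNames(as.numeric(va), labels),
                 labels = labels,
                 household = household),
            class = "flow_table")
}

#' @export
print.flow_table <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("<flow_table> %d sectors, total output %s MUSD%s\n",
              n, fmt_musd(sum(x$x)),
              if (is.null(x$household)) "" else ", household closure data present"))
  shown <- utils::head(x$labels, 6)
  cat("  sectors: ", paste(shown, collapse = ", "),
      if (n > 6) sprintf(", ... (%d more)", n - 6) else "", "\n", sep = "")
  invisible(x)
}

#' Validate a flow table
#'
#' Checks every structural assumption the downstream Leontief analysis relies
#' on: nonnegativity of all accounts, the row (sales) and column (cost)
#' accounting identities to 1e-9 relative tolerance, label uniqueness, and --
#' via the implied coefficient matrix -- the Hawkins-Simon productivity
#' condition.
#'
#' @param table a [flow_table()].
#' @param tol relative tolerance on the accounting identities.
#' @return a data frame of violations with columns `rule`, `sector`,
#'   `magnitude`; zero rows means the table is valid.
#' @export
validate_economy <- function(table, tol = 1e-9) {
  if (!inherits(table, "flow_table")) {
    abort("validate_economy expects a flow_table", "bioecon_structural_error")
  }
  v <- list()
  add <- function(rule, sector, magnitude) {
    v[[length(v) + 1L]] <<- data.frame(rule = rule, sector = sector,
                                       magnitude = magnitude)
  }
  lab <- table$labels
  n <- length(lab)

  neg_check <- function(vals, rule, sectors = lab) {
    bad <- which(vals < 0)
    for (i in bad) add(rule, sectors[i], vals[i])
  }
  neg_z <- which(table$Z < 0, arr.ind = TRUE)
  for (k in seq_len(nrow(neg_z))) {
    add("negative_flow",
        paste0(lab[neg_z[k, 1]], "->", lab[neg_z[k, 2]]),
        table$Z[neg_z[k, 1], neg_z[k, 2]])
  }
  neg_check(table$x, "negative_output")
  neg_check(table$f, "negative_final_demand")
  neg_check(table$va, "negative_value_added")
  if (!is.null(table$household)) {
    neg_check(table$household$consumption, "negative_household_consumption")
    neg_check(table$household$income, "negative_household_income")
  }

  row_err <- rel_err(rowSums(table$Z) + table$f, table$x)
  for (i in which(row_err > tol)) add("row_identity", lab[i], row_err[i])
  col_err <- rel_err(colSums(table$Z) + table$va, table$x)
  for (j in which(col_err > tol)) add("column_identity", lab[j], col_err[j])

  # Productivity of the implied coefficient matrix (only checkable when all
  # outputs are positive; zero output is already reported above via identities
  # or caught by compute_technical_coefficients).
  if (all(table$x > 0)) {
    A <- sweep(table$Z, 2, table$x, "/")
    if (!hawkins_simon(A)) {
      add("hawkins_simon", "(economy)", spectral_radius(A))
    }
  } else {
    for (j in which(table$x <= 0)) add("nonpositive_output", lab[j], table$x[j])
  }

  if (length(v) == 0) {
    data.frame(rule = character(), sector = character(), magnitude = numeric())
  } else {
    do.call(rbind, v)
  }
}

#' Read / write the flow-table CSV dialect
#'
#' The on-disk layout is a single CSV: header `sector,<n sector names>,
#' final_demand,total_output`; one row per sector giving its n sales flows,
#' final demand and total output; a trailing `value_added` row with n values
#' and two empty cells. UTF-8, `.` decimal separator.
#'
#' @param path file path.
#' @return `read_flow_table` returns a [flow_table()]; `write_flow_table`
#'   returns `path` invisibly.
#' @export
read_flow_table <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  hdr <- names(raw)
  if (hdr[1] != "sector" ||
      !identical(utils::tail(hdr, 2), c("final_demand", "total_output"))) {
    abort("not a flow-table CSV: expected header sector,...,final_demand,total_output",
          "bioecon_structural_error")
  }
  labels <- hdr[2:(length(hdr) - 2)]
  n <- length(labels)
  sec_rows <- raw[raw$sector != "value_added", , drop = FALSE]
  va_row <- raw[raw$sector == "value_added", , drop = FALSE]
  if (nrow(sec_rows) != n || nrow(va_row) != 1 ||
      !identical(sec_rows$sector, labels)) {
    abort("flow-table CSV rows do not match header sectors", "bioecon_structural_error")
  }
  Z <- as.matrix(sec_rows[, labels, drop = FALSE])
  rownames(Z) <- labels
  flow_table(Z = Z,
             x = sec_rows$total_output,
             f = sec_rows$final_demand,
             va = as.numeric(va_row[1, labels]),
             labels = labels)
}

#' @rdname read_flow_table
#' @param table a [flow_table()] to serialize.
#' @export
write_flow_table <- function(table, path) {
  stopifnot(inherits(table, "flow_table"))
  lab <- table$labels
  body <- data.frame(sector = lab, table$Z,
                     final_demand = table$f, total_output = table$x,
                     check.names = FALSE, row.names = NULL)
  va <- data.frame(sector = "value_added", t(table$va),
                   final_demand = NA_real_, total_output = NA_real_,
                   check.names = FALSE, row.names = NULL)
  names(va) <- names(body)
  out <- rbind(body, va)
  utils::write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}
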