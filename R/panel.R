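#' Disclosure panel: one manufacturer-year per row, canonical units
#'
#' The central data structure of the package. A `disclosure_panel` is a
#' tibble with one row per (company, year) cell of the disclosure window and
#' columns:
#' \describe{
#'   \item{company, brand, year}{cell identity.}
#'   \item{users}{reported (or imputed) user count, in persons; `NA` if the
#'     manufacturer published none.}
#'   \item{sticks}{annual heated-tobacco stick shipments, in stick units;
#'     `NA` if unpublished.}
#'   \item{users_source, sticks_source}{provenance: `"reported"`,
#'     `"imputed_zero"`, `"imputed_share"`, `"imputed_split"`, or `NA` when
#'     the value is missing.}
#'   \item{domestic_only}{`TRUE` once a reconciliation rule has restricted
#'     the cell to its domestic market.}
#'   \item{domestic_share}{optional fraction of the year's sticks that are
#'     domestic; used by split-carry imputation and reconciliation.}
#'   \item{notes}{free text carried from the input.}
#' }
#' Values are stored in canonical units (persons, stick units); millions and
#' billions exist only at I/O, which removes scale errors from mixed
#' formulas. The index is rectangular: every company x year cell is present
#' even when both values are missing, so inventory denominators are always
#' `n_companies * n_years`.
#'
#' @param records Tibble/data.frame of cells in canonical units with at least
#'   columns `company`, `year`; `brand`, `users`, `sticks`, provenance and
#'   note columns are filled with defaults when absent.
#' @param companies,years The full panel index; cells absent from `records`
#'   are materialized with missing values.
#' @return A `disclosure_panel`.
#' @seealso [read_panel()] to load one from CSV, [htp_table1()] for the
#'   packaged manufacturer disclosure fixture.
#' @export
disclosure_panel <- function(records,
                             companies = unique(records$company),
                             years = sort(unique(records$year))) {
  stopifnot(is.data.frame(records))
  records <- tibble::as_tibble(records)
  if (!all(c("company", "year") %in% names(records))) {
    abort("records need at least 'company' and 'year' columns")
  }
  defaults <- list(
    brand = NA_character_, users = NA_real_, sticks = NA_real_,
    users_source = NA_character_, sticks_source = NA_character_,
    domestic_only = FALSE, domestic_share = NA_real_, notes = NA_character_
  )
  for (col in names(defaults)) {
    if (!col %in% names(records)) records[[col]] <- defaults[[col]]
  }
  unknown <- setdiff(unique(records$company), companies)
  if (length(unknown)) {
    abort(sprintf("unknown company: %s", paste(unknown, collapse = ", ")))
  }
  bad_year <- setdiff(unique(records$year), years)
  if (length(bad_year)) {
    abort(sprintf("year outside panel window: %s",
                  paste(bad_year, collapse = ", ")))
  }
  if (anyDuplicated(records[c("company", "year")])) {
    abort("more than one record per (company, year); run select_latest_vintage() first")
  }
  if (any(records$users < 0, na.rm = TRUE)) abort("negative user count")
  if (any(records$sticks < 0, na.rm = TRUE)) abort("negative stick shipments")

  # materialize the rectangular company x year index
  grid <- tidyr::expand_grid(
    company = factor(companies, levels = companies),
    year = as.integer(years)
  )
  records$company <- factor(records$company, levels = companies)
  records$year <- as.integer(records$year)
  panel <- dplyr::left_join(grid, records, by = c("company", "year"))
  panel <- panel[c("company", "brand", "year", "users", "sticks",
                   "users_source", "sticks_source", "domestic_only",
                   "domestic_share", "notes")]
  panel$domestic_only[is.na(panel$domestic_only)] <- FALSE
  # infer provenance for values that arrived without flags
  panel$users_source[is.na(panel$users_source) & !is.na(panel$users)] <- "reported"
  panel$sticks_source[is.na(panel$sticks_source) & !is.na(panel$sticks)] <- "reported"

  structure(panel,
            class = c("disclosure_panel", class(tibble::tibble())),
            companies = companies, years = as.integer(years),
            log = character())
}

#' @export
print.disclosure_panel <- function(x, ...) {
  cat(sprintf("<disclosure_panel> %d companies x %d years (%d cells)\n",
              length(attr(x, "companies")), length(attr(x, "years")),
              nrow(x)))
  nlog <- length(attr(x, "log"))
  if (nlog) cat(sprintf("  %d logged action(s); see panel_log()\n", nlog))
  NextMethod()
}

#' Load a disclosure panel from CSV
#'
#' Reads a delimited table with header
#' `company,brand,year,users_millions,sticks_billions,report_vintage,notes`
#' (an optional `domestic_share` column is carried through). `"N/A"`, `"NA"`
#' and empty cells are missing; `"0.0"` is the numeric value zero, i.e. a
#' reported disclosure, not a gap. Values are canonicalized to persons and
#' stick units. When several vintages of the same company-year are present,
#' the latest-vintage record is retained via [select_latest_vintage()].
#'
#' @param path CSV file path.
#' @param companies,years Panel index; defaults to the four included
#'   manufacturers (PMI, KT&G, BAT, JT) over 2014-2024.
#' @return A [disclosure_panel]; an empty file yields an empty panel.
#' @export
#' @examples
#' panel <- read_panel(heatcount_example("table1_disclosures.csv"))
#' inventory_stats(panel)
read_panel <- function(path, companies = PANEL_COMPANIES,
                       years = PANEL_YEARS) {
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      company = readr::col_character(),
      brand = readr::col_character(),
      year = readr::col_integer(),
      users_millions = readr::col_double(),
      sticks_billions = readr::col_double(),
      report_vintage = readr::col_character(),
      notes = readr::col_character(),
      .default = readr::col_double()
    ),
    na = c("", "NA", "N/A")
  ))
  probs <- readr::problems(raw)
  if (nrow(probs)) {
    abort(sprintf("malformed cell at row %d, column '%s': expected %s, got '%s'",
                  probs$row[1], names(raw)[probs$col[1]],
                  probs$expected[1], probs$actual[1]))
  }
  if (nrow(raw) == 0) {
    return(disclosure_panel(
      tibble::tibble(company = character(), year = integer()),
      companies = character(), years = integer()
    ))
  }
  if (!"report_vintage" %in% names(raw)) raw$report_vintage <- NA_character_
  triple <- paste(raw$company, raw$year, raw$report_vintage, sep = "\r")
  if (anyDuplicated(triple)) {
    dup <- raw[duplicated(triple), , drop = FALSE]
    abort(sprintf("duplicate (company, year, vintage) disclosure: %s %d",
                  dup$company[1], dup$year[1]))
  }
  key <- paste(raw$company, raw$year, sep = "\r")
  raw <- dplyr::bind_rows(lapply(split(raw, key), select_latest_vintage))

  records <- tibble::tibble(
    company = raw$company,
    brand = raw$brand,
    year = raw$year,
    users = raw$users_millions * 1e6,
    sticks = raw$sticks_billions * 1e9,
    domestic_share = if ("domestic_share" %in% names(raw)) raw$domestic_share else NA_real_,
    notes = raw$notes
  )
  disclosure_panel(records, companies = companies, years = years)
}

#' Keep the most recent disclosure for a company-year
#'
#' Manufacturers revise historical figures in later reports; when several
#' vintages of the same company-year exist, the latest published figure
#' wins. Records without a vintage lose to any dated record. Two records
#' sharing the maximal vintage but disagreeing on values is an ambiguity the
#' rule cannot resolve and raises an error. Selection is idempotent and
#' independent of input order.
#'
#' @param records Data frame of one or more rows for a single (company,
#'   year), with a `report_vintage` column of ordinally comparable strings
#'   (ISO dates or years).
#' @return The single retained row.
#' @export
select_latest_vintage <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  if (nrow(records) == 1) return(records)
  if (length(unique(records$company)) > 1 || length(unique(records$year)) > 1) {
    abort("select_latest_vintage() expects records for a single (company, year)")
  }
  vintage <- as.character(records$report_vintage)
  dated <- !is.na(vintage)
  if (any(dated)) {
    records <- records[dated, , drop = FALSE]
    vintage <- vintage[dated]
  }
  latest <- records[vintage == max(vintage) | all(!dated), , drop = FALSE]
  value_cols <- intersect(c("users_millions", "sticks_billions", "users", "sticks"),
                          names(latest))
  if (nrow(latest) > 1 && nrow(unique(latest[value_cols])) > 1) {
    abort(sprintf("ambiguous vintages for %s %d: identical maximal vintage, different values",
                  latest$company[1], latest$year[1]))
  }
  latest[1, , drop = FALSE]
}

#' Write a panel back to input units
#'
#' Inverse of [read_panel()]: users in millions and sticks in billions at one
#' decimal, missing values as `"N/A"`. Writing a loaded panel and reloading
#' it reproduces the panel exactly, because disclosures are printed at that
#' display precision in the first place.
#'
#' @param panel A [disclosure_panel].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  fmt <- function(x, scale) ifelse(is.na(x), "N/A", sprintf("%.1f", x / scale))
  out <- tibble::tibble(
    company = as.character(panel$company),
    brand = panel$brand,
    year = panel$year,
    users_millions = fmt(panel$users, 1e6),
    sticks_billions = fmt(panel$sticks, 1e9),
    report_vintage = NA_character_,
    notes = panel$notes
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' The packaged manufacturer disclosure panel
#'
#' Loads the fixture transcribing the published company-year table of HTP
#' user counts (millions) and stick shipments (billions) for PMI (IQOS),
#' KT&G (lil), BAT (glo) and JT (Ploom), 2014-2024.
#'
#' @return A [disclosure_panel] of 44 cells.
#' @export
htp_table1 <- function() {
  read_panel(heatcount_example("table1_disclosures.csv"))
}

#' Inventory a disclosure panel
#'
#' Classifies every company-year cell as users-reported (a user count is
#' present, explicit zeros included), sticks-only (no user count but a
#' shipment volume, zeros included), or neither. The three classes partition
#' the panel, so counts always sum to the number of cells.
#'
#' @param panel A [disclosure_panel].
#' @return A `data_inventory`: list with counts `n_total`,
#'   `n_users_reported`, `n_sticks_only`, `n_neither`, `n_any`, matching
#'   percentages (`pct_*`, of `n_total`), and `cells`, the per-cell
#'   classification tibble.
#' @export
#' @examples
#' inventory_stats(htp_table1())
inventory_stats <- function(panel) {
  stopifnot(inherits(panel, "disclosure_panel"))
  class_of <- ifelse(!is.na(panel$users), "users_reported",
              ifelse(!is.na(panel$sticks), "sticks_only", "neither"))
  cells <- tibble::tibble(company = panel$company, year = panel$year,
                          class = class_of)
  n_total <- nrow(cells)
  counts <- c(
    n_users_reported = sum(class_of == "users_reported"),
    n_sticks_only = sum(class_of == "sticks_only"),
    n_neither = sum(class_of == "neither")
  )
  pct <- if (n_total > 0) round_half_away(100 * counts / n_total, 1) else counts * NA_real_
  structure(list(
    n_total = n_total,
    n_users_reported = unname(counts[1]),
    n_sticks_only = unname(counts[2]),
    n_neither = unname(counts[3]),
    n_any = n_total - unname(counts[3]),
    pct_users_reported = unname(pct[1]),
    pct_sticks_only = unname(pct[2]),
    pct_neither = unname(pct[3]),
    pct_any = if (n_total > 0) round_half_away(100 * (n_total - unname(counts[3])) / n_total, 1) else NA_real_,
    cells = cells
  ), class = "data_inventory")
}

#' @export
print.data_inventory <- function(x, ...) {
  cat(sprintf("<data_inventory> %d company-year cells\n", x$n_total))
  cat(sprintf("  users reported : %d (%.1f%%)\n", x$n_users_reported, x$pct_users_reported))
  cat(sprintf("  sticks only    : %d (%.1f%%)\n", x$n_sticks_only, x$pct_sticks_only))
  cat(sprintf("  neither        : %d (%.1f%%)\n", x$n_neither, x$pct_neither))
  cat(sprintf("  >=1 data point : %d (%.1f%%)\n", x$n_any, x$pct_any))
  invisible(x)
}
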