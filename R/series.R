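#' Annual global user series
#'
#' An `htp_series` is a tibble with one row per year and columns `year`,
#' `total_central`, `total_lower`, `total_upper` (persons). The per-company
#' decomposition is carried alongside (see [company_breakdown()]) and every
#' total — central and each bound — is the exact sum of its company
#' components. `variant` records which estimator produced it (`"primary"`,
#' `"alternative"`, or `"survey"`).
#'
#' @param per_company Long tibble with columns `company`, `year`, `central`,
#'   `lower`, `upper`, `method`.
#' @param variant Series variant label.
#' @return An `htp_series`.
#' @export
htp_series <- function(per_company, variant = c("primary", "alternative", "survey")) {
  variant <- match.arg(variant)
  per_company <- tibble::as_tibble(per_company)
  bad <- with(per_company, lower > central | central > upper)
  if (any(bad)) abort("bound ordering violated: need lower <= central <= upper")
  totals <- per_company |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(total_central = sum(.data$central),
                     total_lower = sum(.data$lower),
                     total_upper = sum(.data$upper), .groups = "drop") |>
    dplyr::arrange(.data$year)
  structure(totals,
            class = c("htp_series", class(tibble::tibble())),
            per_company = per_company, variant = variant)
}

#' @export
print.htp_series <- function(x, ...) {
  cat(sprintf("<htp_series> variant: %s (%d years, totals in persons)\n",
              attr(x, "variant"), nrow(x)))
  NextMethod()
}

#' Series variant label
#' @param series An [htp_series].
#' @return `"primary"`, `"alternative"`, or `"survey"`.
#' @export
series_variant <- function(series) attr(series, "variant")

#' Per-company annual breakdown of a series
#'
#' Long-format table (company, year, central, lower, upper, method) whose
#' yearly sums equal the series totals exactly.
#'
#' @param series An [htp_series].
#' @return A tibble; empty for an empty series.
#' @export
company_breakdown <- function(series) {
  stopifnot(inherits(series, "htp_series"))
  attr(series, "per_company")
}

# resolve one company-year cell into a user estimate
resolve_cell <- function(users, sticks, users_source, assumption,
                         company, year) {
  if (!is.na(users)) {
    method <- if (identical(users_source, "imputed_zero")) "imputed_zero" else "reported"
    return(tibble::tibble(company = company, year = year, central = users,
                          lower = users, upper = users, method = method))
  }
  if (!is.na(sticks)) {
    if (is.null(assumption)) {
      abort(sprintf("no consumption assumption for %s %d: cannot convert sticks",
                    company, year))
    }
    central <- sticks_to_users(sticks, assumption)
    b <- sensitivity_bounds(central, "converted", assumption)
    return(tibble::tibble(company = company, year = year, central = central,
                          lower = b$lower, upper = b$upper,
                          method = "converted"))
  }
  NULL
}

#' Build the primary disclosure-based series
#'
#' For every company-year, uses the reported user count when one exists
#' (reported counts carry no sensitivity, so their bounds equal the central
#' value); otherwise converts the shipment volume with the company's brand
#' consumption assumption and attaches that assumption's sensitivity bounds
#' (+/-50% user-space by default). Company estimates are summed per year
#' into global totals. The panel must already be imputed and reconciled:
#' any cell that resolves to neither a reported value, a conversion, nor a
#' rule imputation is a hard coverage error, never a silent zero.
#'
#' @param panel An imputed, reconciled [disclosure_panel].
#' @param assumptions Named list of [consumption_assumption] keyed by
#'   company; defaults to [default_assumptions()] calibrated on `panel`.
#' @return An [htp_series] with `variant = "primary"`.
#' @export
#' @examples
#' panel <- reconcile_overlap(impute_panel(htp_table1()))
#' series <- build_primary_series(panel)
#' series[series$year == 2024, ]
build_primary_series <- function(panel, assumptions = default_assumptions(panel)) {
  stopifnot(inherits(panel, "disclosure_panel"))
  uncovered <- is.na(panel$users) & is.na(panel$sticks)
  if (any(uncovered)) {
    cells <- paste(panel$company[uncovered], panel$year[uncovered],
                   collapse = ", ")
    abort(sprintf("coverage error: no reported value, conversion, or imputation for: %s",
                  cells))
  }
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    resolve_cell(panel$users[i], panel$sticks[i], panel$users_source[i],
                 assumptions[[as.character(panel$company[i])]],
                 as.character(panel$company[i]), panel$year[i])
  })
  htp_series(dplyr::bind_rows(rows), variant = "primary")
}

#' Build the alternative shipment-only series
#'
#' Ignores every manufacturer-reported user count and converts all
#' companies' stick shipments with one common literature-based consumption
#' parameter (default 7.3 sticks/day). Bounds come from the parameter's 95%
#' CI: the upper endpoint (8.27) gives the lower user bound, the lower
#' endpoint (6.33) the upper bound. Every company-year must have a shipment
#' volume (possibly zero) after imputation.
#'
#' @param panel An imputed, reconciled [disclosure_panel].
#' @param literature A [consumption_assumption] in `parameter_ci_bounds`
#'   mode; defaults to [literature_consumption()].
#' @return An [htp_series] with `variant = "alternative"`.
#' @export
#' @examples
#' panel <- reconcile_overlap(impute_panel(htp_table1()))
#' build_alternative_series(panel)
build_alternative_series <- function(panel, literature = literature_consumption()) {
  stopifnot(inherits(panel, "disclosure_panel"))
  if (anyNA(panel$sticks)) {
    cells <- paste(panel$company[is.na(panel$sticks)],
                   panel$year[is.na(panel$sticks)], collapse = ", ")
    abort(sprintf("coverage error: missing sticks after imputation for: %s", cells))
  }
  central <- sticks_to_users(panel$sticks, literature)
  b <- sensitivity_bounds(central, "converted", literature)
  per_company <- tibble::tibble(
    company = as.character(panel$company), year = panel$year,
    central = central, lower = b$lower, upper = b$upper,
    method = "converted"
  )
  htp_series(per_company, variant = "alternative")
}

#' Write a series to CSV/JSON
#'
#' Writes the annual totals as CSV (`year,total_central,total_lower,
#' total_upper`), the per-company breakdown as a second CSV, and optionally
#' a JSON mirror of both.
#'
#' @param series An [htp_series].
#' @param path Totals CSV path; the breakdown goes to
#'   `<path>_companies.csv` and the JSON mirror to `<path>.json`.
#' @param json Also write the JSON mirror.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, json = FALSE) {
  readr::write_csv(tibble::as_tibble(series), path)
  stem <- sub("\\.csv$", "", path)
  readr::write_csv(company_breakdown(series),
                   paste0(stem, "_companies.csv"))
  if (json) {
    jsonlite::write_json(
      list(variant = series_variant(series),
           totals = tibble::as_tibble(series),
           companies = company_breakdown(series)),
      paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
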