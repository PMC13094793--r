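#' Country user count from survey prevalence
#'
#' Multiplies a nationally representative current-use prevalence by the
#' cohort population: `users = round(prevalence/100 * population * 1000)`,
#' with the population supplied in thousands and rounding to the nearest
#' whole person, ties half away from zero.
#'
#' @param prevalence Current HTP use prevalence, percent, in \[0, 100\].
#'   Vectorized.
#' @param population_thousands Cohort population, thousands of persons;
#'   positive.
#' @return Users, persons (integer-valued).
#' @export
#' @examples
#' users_from_prevalence(5.00, 1117.9)   # 55895
users_from_prevalence <- function(prevalence, population_thousands) {
  if (any(prevalence < 0 | prevalence > 100, na.rm = TRUE)) {
    abort("prevalence must lie in [0, 100] percent")
  }
  if (any(population_thousands <= 0, na.rm = TRUE)) {
    abort("population must be positive")
  }
  round_half_away(prevalence / 100 * population_thousands * 1000)
}

#' Load a country survey table
#'
#' Reads a CSV with columns `country, prevalence_pct, year, survey, cohort,
#' population_thousands` and optionally `users_printed` (the user count as
#' printed in the source). A `users_recomputed` column is always derived via
#' [users_from_prevalence()]; `users` is the printed value when available
#' (some sources computed their cells from unrounded denominators, so the
#' printed column is authoritative), else the recomputation.
#'
#' @param path CSV path; defaults to the packaged 35-country table.
#' @return Tibble of survey records, one per country.
#' @export
read_survey_table <- function(path = heatcount_example("table2_surveys.csv")) {
  rec <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    country = readr::col_character(),
    prevalence_pct = readr::col_double(),
    year = readr::col_integer(),
    survey = readr::col_character(),
    cohort = readr::col_character(),
    population_thousands = readr::col_double(),
    .default = readr::col_double()
  ), na = c("", "NA", "N/A")))
  probs <- readr::problems(rec)
  if (nrow(probs)) {
    abort(sprintf("malformed cell at row %d of survey table", probs$row[1]))
  }
  rec$users_recomputed <- users_from_prevalence(rec$prevalence_pct,
                                                rec$population_thousands)
  rec$users <- if ("users_printed" %in% names(rec)) {
    ifelse(is.na(rec$users_printed), rec$users_recomputed, rec$users_printed)
  } else {
    rec$users_recomputed
  }
  rec
}

#' The packaged national survey prevalence table
#'
#' Current HTP use prevalence, survey year and cohort, population
#' denominators, and printed user counts for the 35 countries with
#' nationally representative data.
#'
#' @return Tibble of 35 survey records.
#' @export
htp_table2 <- function() {
  read_survey_table()
}

#' Aggregate country survey estimates
#'
#' Sums the country user counts and ranks the largest contributors. The
#' total is a conservative lower bound on global use, not a competing
#' global estimate: surveyed countries are fewer than half of those where
#' the products are sold.
#'
#' @param records Survey table from [read_survey_table()], one row per
#'   country (a `users` column in persons).
#' @param top_k Number of top contributors to report.
#' @return A `survey_aggregate`: list with `n_countries`, `total_users`,
#'   `top_contributors` (tibble country/users, ties broken by country label
#'   order), and `top_k_share` (percent of the total).
#' @export
#' @examples
#' aggregate_survey(htp_table2(), top_k = 5)
aggregate_survey <- function(records, top_k = 5) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  if (anyDuplicated(records$country)) {
    dup <- records$country[duplicated(records$country)][1]
    abort(sprintf("duplicate country in survey table: %s", dup))
  }
  top_k <- min(top_k, nrow(records))
  total <- sum(records$users)
  ranked <- records[order(-records$users, records$country), c("country", "users")]
  top <- utils::head(ranked, top_k)
  structure(list(
    n_countries = nrow(records),
    total_users = total,
    top_contributors = tibble::as_tibble(top),
    top_k_share = if (total > 0) 100 * sum(top$users) / total else NA_real_
  ), class = "survey_aggregate")
}

#' @export
print.survey_aggregate <- function(x, ...) {
  cat(sprintf("<survey_aggregate> %d countries, %s users\n",
              x$n_countries, format(x$total_users, big.mark = ",")))
  cat(sprintf("  top %d countries hold %.1f%% of the total:\n",
              nrow(x$top_contributors), x$top_k_share))
  for (i in seq_len(nrow(x$top_contributors))) {
    cat(sprintf("    %-12s %s\n", x$top_contributors$country[i],
                format(x$top_contributors$users[i], big.mark = ",")))
  }
  invisible(x)
}
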