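#' Define a synthetic HTP market scenario
#'
#' Describes a market with known ground truth for recovery testing. Each
#' company's true user base follows logistic uptake,
#' `users(t) = K / (1 + exp(-r (t - t0)))` for years at or after launch and
#' zero before — the simplest monotone curve with saturation, matching the
#' observed pattern of near-zero launch years, accelerated expansion, and
#' sustained growth. True shipments are definitionally
#' `users * c * 365`, optionally perturbed by multiplicative lognormal noise
#' (users are truth; only the shipment channel is noisy). A disclosure
#' pattern then masks each cell the way manufacturers disclose selectively,
#' and display rounding (users to 0.1 million, sticks to 0.1 billion)
#' emulates how figures are printed.
#'
#' @param companies Data frame with columns `name`, `launch_year`, `K`
#'   (carrying capacity, persons), `r` (growth rate, per year), `t0`
#'   (midpoint year), `c` (mean daily consumption, sticks/day).
#' @param years Calendar years of the panel.
#' @param shipment_noise_sd Lognormal sigma of the multiplicative shipment
#'   noise; 0 for a noiseless market. Default 0.05 (about +/-5% reporting
#'   noise).
#' @param disclosure_pattern Either a single mask applied to every cell or a
#'   data frame (`company`, `year`, `mask`) covering every company-year;
#'   masks are `"both"`, `"users_only"`, `"sticks_only"`, `"none"`.
#' @param display_rounding Apply display rounding to the masked panel.
#' @param seed Integer seed; generation is a pure function of
#'   (scenario, seed).
#' @return A `market_scenario`.
#' @export
market_scenario <- function(companies, years = 2014:2024,
                            shipment_noise_sd = 0.05,
                            disclosure_pattern = "both",
                            display_rounding = TRUE, seed = 1L) {
  companies <- tibble::as_tibble(companies)
  needed <- c("name", "launch_year", "K", "r", "t0", "c")
  if (!all(needed %in% names(companies))) {
    abort(sprintf("companies needs columns: %s", paste(needed, collapse = ", ")))
  }
  if (any(companies$K < 0)) abort("carrying capacity K must be >= 0")
  if (any(companies$r <= 0)) abort("growth rate r must be > 0")
  if (any(companies$c <= 0)) abort("mean consumption c must be > 0")
  years <- as.integer(years)
  masks <- c("both", "users_only", "sticks_only", "none")
  if (is.character(disclosure_pattern) && length(disclosure_pattern) == 1) {
    if (!disclosure_pattern %in% masks) abort("unknown disclosure mask")
    grid <- tidyr::expand_grid(company = companies$name, year = years)
    grid$mask <- disclosure_pattern
    disclosure_pattern <- grid
  } else {
    disclosure_pattern <- tibble::as_tibble(disclosure_pattern)
    if (!all(disclosure_pattern$mask %in% masks)) abort("unknown disclosure mask")
    want <- tidyr::expand_grid(company = companies$name, year = years)
    got <- disclosure_pattern[c("company", "year")]
    if (nrow(dplyr::anti_join(want, got, by = c("company", "year"))) ||
        nrow(dplyr::anti_join(got, want, by = c("company", "year")))) {
      abort("disclosure pattern must cover every company-year of the scenario, and no others")
    }
  }
  structure(list(companies = companies, years = years,
                 shipment_noise_sd = shipment_noise_sd,
                 disclosure_pattern = disclosure_pattern,
                 display_rounding = display_rounding,
                 seed = as.integer(seed)),
            class = "market_scenario")
}

#' Generate a synthetic market
#'
#' Realizes a [market_scenario()] into a ground-truth panel and the masked,
#' display-rounded panel a surveillance analyst would actually observe. The
#' masked panel is a regular [disclosure_panel], so it feeds the estimation
#' pipeline unchanged. Identical scenarios (including seed) give identical
#' output; the caller's RNG state is left untouched.
#'
#' @param scenario A [market_scenario].
#' @return List with `truth` (unmasked, unrounded [disclosure_panel]),
#'   `panel` (masked observed panel), and `truth_totals` (tibble of true
#'   global users per year).
#' @export
#' @examples
#' sc <- market_scenario(
#'   tibble::tibble(name = "A", launch_year = 2015, K = 5e6, r = 0.8,
#'                  t0 = 2019, c = 7.3),
#'   shipment_noise_sd = 0, seed = 7)
#' generate_market(sc)$truth_totals
generate_market <- function(scenario) {
  stopifnot(inherits(scenario, "market_scenario"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(scenario$seed)

  cells <- tidyr::expand_grid(ci = seq_len(nrow(scenario$companies)),
                              year = scenario$years)
  co <- scenario$companies[cells$ci, ]
  users <- ifelse(cells$year >= co$launch_year,
                  co$K / (1 + exp(-co$r * (cells$year - co$t0))), 0)
  noise <- if (scenario$shipment_noise_sd > 0) {
    exp(rnorm(nrow(cells), 0, scenario$shipment_noise_sd))
  } else 1
  sticks <- users * co$c * 365 * noise

  truth_records <- tibble::tibble(company = co$name, year = cells$year,
                                  users = users, sticks = sticks)
  truth <- disclosure_panel(truth_records,
                            companies = scenario$companies$name,
                            years = scenario$years)

  obs <- dplyr::left_join(truth_records, scenario$disclosure_pattern,
                          by = c("company", "year"))
  obs$users[!obs$mask %in% c("both", "users_only")] <- NA_real_
  obs$sticks[!obs$mask %in% c("both", "sticks_only")] <- NA_real_
  if (scenario$display_rounding) {
    obs$users <- round_half_away(obs$users / 1e5) * 1e5    # 0.1 million
    obs$sticks <- round_half_away(obs$sticks / 1e8) * 1e8  # 0.1 billion
  }
  panel <- disclosure_panel(obs[c("company", "year", "users", "sticks")],
                            companies = scenario$companies$name,
                            years = scenario$years)
  truth_totals <- truth_records |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(users = sum(.data$users), .groups = "drop")
  list(truth = truth, panel = panel, truth_totals = truth_totals)
}

#' Quantify recovery of true user totals by an estimated series
#'
#' Compares an estimated global series with the generator's ground truth:
#' per-year relative error of the central estimate, whether the truth lies
#' inside the (lower, upper) band, and optionally the bias of a calibrated
#' consumption parameter against the generating one.
#'
#' @param series An [htp_series] built from the masked panel.
#' @param truth Either the truth panel from [generate_market()] or a tibble
#'   of true totals (`year`, `users`).
#' @param true_consumption,estimated_consumption Optional sticks/day values
#'   to report a consumption-parameter bias.
#' @return A `recovery_report`: list with `per_year` (tibble `year`, `truth`,
#'   `estimate`, `rel_error`, `covered`) and `consumption_bias` (relative;
#'   `NA` when not assessed). Relative error is 0 when both truth and
#'   estimate are zero.
#' @export
recovery_report <- function(series, truth,
                            true_consumption = NULL,
                            estimated_consumption = NULL) {
  stopifnot(inherits(series, "htp_series"))
  if (inherits(truth, "disclosure_panel")) {
    truth <- tibble::as_tibble(truth) |>
      dplyr::group_by(.data$year) |>
      dplyr::summarise(users = sum(.data$users), .groups = "drop")
  }
  truth <- tibble::as_tibble(truth)
  if (!setequal(truth$year, series$year)) {
    abort("year mismatch between estimated series and truth")
  }
  joined <- dplyr::inner_join(tibble::as_tibble(series), truth, by = "year")
  rel <- ifelse(joined$users == 0 & joined$total_central == 0, 0,
                (joined$total_central - joined$users) / joined$users)
  per_year <- tibble::tibble(
    year = joined$year, truth = joined$users,
    estimate = joined$total_central, rel_error = rel,
    covered = joined$total_lower <= joined$users &
      joined$users <= joined$total_upper
  )
  bias <- if (!is.null(true_consumption) && !is.null(estimated_consumption)) {
    (estimated_consumption - true_consumption) / true_consumption
  } else NA_real_
  structure(list(per_year = per_year, consumption_bias = bias),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d years; max |relative error| %.3g; %d/%d covered\n",
              nrow(x$per_year), max(abs(x$per_year$rel_error)),
              sum(x$per_year$covered), nrow(x$per_year)))
  if (!is.na(x$consumption_bias)) {
    cat(sprintf("  consumption parameter bias: %+.3g%%\n",
                100 * x$consumption_bias))
  }
  invisible(x)
}
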