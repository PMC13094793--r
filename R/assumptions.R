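#' Brand consumption assumption
#'
#' Bundles a mean daily stick consumption per user (sticks/day) with the rule
#' used to form sensitivity bounds around user counts converted with it:
#' \describe{
#'   \item{`multiplicative_user_bounds`}{bounds are +/-50% on the converted
#'     user count (x0.5, x1.5); the primary-series convention.}
#'   \item{`parameter_ci_bounds`}{bounds re-run the conversion at the upper
#'     and lower consumption CI endpoints (`upper_param` gives the lower user
#'     bound and vice versa); the shipment-only-series convention.}
#'   \item{`none`}{bounds collapse onto the central value.}
#' }
#'
#' @param central Sticks per user per day; must be positive.
#' @param mode Bounding rule, one of the three above.
#' @param lower_param,upper_param Consumption CI endpoints (sticks/day),
#'   required for `parameter_ci_bounds`; must bracket `central`.
#' @param companies Companies the assumption applies to (informational).
#' @param provenance Free-text origin, e.g. the donor calibration.
#' @return A `consumption_assumption`.
#' @export
#' @examples
#' consumption_assumption(7.3, mode = "parameter_ci_bounds",
#'                        lower_param = 6.33, upper_param = 8.27)
consumption_assumption <- function(central,
                                   mode = c("multiplicative_user_bounds",
                                            "parameter_ci_bounds", "none"),
                                   lower_param = NULL, upper_param = NULL,
                                   companies = character(),
                                   provenance = NA_character_) {
  mode <- match.arg(mode)
  if (!is.numeric(central) || length(central) != 1 || !is.finite(central) ||
      central <= 0) {
    abort("central consumption must be a single positive number (sticks/day)")
  }
  if (!is.null(lower_param) || !is.null(upper_param)) {
    if (is.null(lower_param) || is.null(upper_param)) {
      abort("supply both lower_param and upper_param, or neither")
    }
    if (!(lower_param <= central && central <= upper_param)) {
      abort("consumption CI must bracket the central value: lower <= central <= upper")
    }
  }
  if (mode == "parameter_ci_bounds" && is.null(lower_param)) {
    abort("parameter_ci_bounds mode needs lower_param and upper_param")
  }
  structure(list(central = central, lower_param = lower_param,
                 upper_param = upper_param, mode = mode,
                 companies = companies, provenance = provenance),
            class = "consumption_assumption")
}

#' @export
print.consumption_assumption <- function(x, ...) {
  ci <- if (!is.null(x$lower_param)) {
    sprintf(" [%g, %g]", x$lower_param, x$upper_param)
  } else ""
  cat(sprintf("<consumption_assumption> %g sticks/day%s, bounds: %s\n",
              x$central, ci, x$mode))
  if (!is.na(x$provenance)) cat(" ", x$provenance, "\n")
  invisible(x)
}

#' Literature-based common consumption parameter
#'
#' The survey-derived mean daily consumption used by the shipment-only
#' series: 7.3 sticks per day with 95% CI 6.33-8.27 (German current-user
#' surveys, 2018-2023; Italian estimates are comparable at 7.9).
#'
#' @param central,ci Override the default parameter or CI.
#' @return A [consumption_assumption] in `parameter_ci_bounds` mode.
#' @export
literature_consumption <- function(central = 7.3, ci = c(6.33, 8.27)) {
  consumption_assumption(central, mode = "parameter_ci_bounds",
                         lower_param = ci[1], upper_param = ci[2],
                         provenance = "literature mean daily consumption, 95% CI")
}

#' Calibrate a brand consumption parameter from dual-disclosure years
#'
#' For every donor company-year in which both a user count and a shipment
#' volume were published (both strictly positive), computes the implied
#' daily consumption `sticks / (users * 365)` and returns the arithmetic
#' mean of the per-year ratios, rounded to the requested precision. The mean
#' of ratios (not the ratio of sums) is used so each disclosure year carries
#' equal weight regardless of market size.
#'
#' @param panel A [disclosure_panel].
#' @param donor Company whose dual-disclosure years drive the calibration.
#' @param digits Rounding precision of the returned parameter (0 for the
#'   KT&G assumption, 1 for BAT/JT).
#' @param mode Bounding rule attached to the resulting assumption.
#' @return A [consumption_assumption] whose provenance lists the
#'   contributing years and the unrounded mean.
#' @export
#' @examples
#' calibrate_consumption(htp_table1(), donor = "PMI", digits = 0)
calibrate_consumption <- function(panel, donor, digits = 1,
                                  mode = "multiplicative_user_bounds") {
  stopifnot(inherits(panel, "disclosure_panel"))
  rows <- panel[panel$company == donor &
                  !is.na(panel$users) & !is.na(panel$sticks) &
                  panel$users > 0 & panel$sticks > 0, , drop = FALSE]
  if (nrow(rows) == 0) {
    abort(sprintf("no dual-disclosure year for donor '%s': cannot calibrate", donor))
  }
  ratios <- implied_daily_consumption(rows$sticks, rows$users)
  central <- round_half_away(mean(ratios), digits)
  consumption_assumption(
    central, mode = mode,
    provenance = sprintf("mean of %d yearly implied ratios from %s %s (unrounded %.4f)",
                         nrow(rows), donor,
                         paste(range(rows$year), collapse = "-"),
                         mean(ratios))
  )
}

#' Read brand consumption assumptions from a YAML config
#'
#' The config has a `brands` map (per-company entries with `central`, `mode`,
#' optional `lower_param`/`upper_param`, `donor`, `rounding`) and an optional
#' `literature` block (`central`, `ci`). When an entry carries a `donor`, the
#' parameter may be recalibrated from a supplied panel instead of trusting
#' the stored central value.
#'
#' @param path YAML file; defaults to the packaged assumptions.
#' @param panel Optional [disclosure_panel]; when supplied, entries with a
#'   `donor` are recalibrated from it via [calibrate_consumption()].
#' @return List with `brands` (named list of [consumption_assumption]) and
#'   `literature` (a [consumption_assumption] or `NULL`).
#' @export
read_assumptions <- function(path = heatcount_example("assumptions.yaml"),
                             panel = NULL) {
  cfg <- yaml::read_yaml(path)
  brands <- lapply(names(cfg$brands), function(nm) {
    entry <- cfg$brands[[nm]]
    mode <- entry$mode %||% "multiplicative_user_bounds"
    if (!is.null(panel) && !is.null(entry$donor)) {
      calibrate_consumption(panel, donor = entry$donor,
                            digits = entry$rounding %||% 1, mode = mode)
    } else {
      consumption_assumption(entry$central, mode = mode,
                             lower_param = entry$lower_param,
                             upper_param = entry$upper_param,
                             companies = nm,
                             provenance = if (!is.null(entry$donor)) {
                               sprintf("calibrated from donor %s", entry$donor)
                             } else NA_character_)
    }
  })
  names(brands) <- names(cfg$brands)
  literature <- if (!is.null(cfg$literature)) {
    literature_consumption(cfg$literature$central,
                           ci = unlist(cfg$literature$ci))
  }
  list(brands = brands, literature = literature)
}

#' Default brand assumptions for the primary series
#'
#' KT&G: 12 sticks/day (calibrated from PMI dual-disclosure years, rounded
#' to the integer); BAT and JT: 7.6 sticks/day (calibrated from BAT dual
#' years, one decimal). All use multiplicative +/-50% user-space bounds.
#'
#' @param panel Panel to calibrate from; defaults to the packaged
#'   disclosure table.
#' @return Named list of [consumption_assumption], keyed by company.
#' @export
default_assumptions <- function(panel = htp_table1()) {
  kt <- calibrate_consumption(panel, donor = "PMI", digits = 0)
  bj <- calibrate_consumption(panel, donor = "BAT", digits = 1)
  list(`KT&G` = kt, BAT = bj, JT = bj)
}
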