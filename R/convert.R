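#' Convert stick shipments to implied users
#'
#' The core estimator: `users = sticks / (c * 365)`, where `c` is mean daily
#' stick consumption per user. The year length is exactly 365 days; the
#' result is exact and real-valued, with rounding deferred to reporting.
#'
#' @param sticks Annual shipments in stick units; non-negative. Vectorized.
#' @param assumption A [consumption_assumption], or a bare positive number of
#'   sticks/day.
#' @return Implied users, in persons.
#' @export
#' @examples
#' sticks_to_users(8.3e9, 12)   # ~1.895 million
sticks_to_users <- function(sticks, assumption) {
  c_day <- if (inherits(assumption, "consumption_assumption")) {
    assumption$central
  } else {
    assumption
  }
  if (!is.numeric(c_day) || any(!is.finite(c_day)) || any(c_day <= 0)) {
    abort("daily consumption must be positive (sticks/day)")
  }
  if (any(sticks < 0, na.rm = TRUE)) abort("negative stick shipments")
  sticks / (c_day * 365)
}

#' Implied daily consumption from a dual disclosure
#'
#' Inverse of [sticks_to_users()]: the per-user daily stick consumption a
#' company-year implies when both its user count and shipment volume are
#' published, `sticks / (users * 365)`.
#'
#' @param sticks Annual shipments, stick units; non-negative.
#' @param users User count, persons; strictly positive.
#' @return Sticks per user per day. Vectorized.
#' @export
implied_daily_consumption <- function(sticks, users) {
  if (any(users <= 0, na.rm = TRUE)) {
    abort("implied consumption undefined for users <= 0")
  }
  if (any(sticks < 0, na.rm = TRUE)) abort("negative stick shipments")
  sticks / (users * 365)
}

#' Sensitivity bounds around a user estimate
#'
#' Directly reported user counts carry no sensitivity: their bounds equal
#' the central value, as do imputed zeros. For shipment-converted estimates
#' the bound depends on the assumption's mode: multiplicative user-space
#' bounds are x0.5 / x1.5 of the central count (+/-50%); parameter-CI bounds
#' re-run the conversion at the CI endpoints, so the upper consumption
#' parameter yields the lower user bound and vice versa.
#'
#' @param central Central user estimate, persons; non-negative. Vectorized.
#' @param method `"reported"`, `"imputed_zero"`, or `"converted"`.
#' @param assumption The [consumption_assumption] the conversion used;
#'   required when `method = "converted"`.
#' @return List with numeric `lower` and `upper` (persons), satisfying
#'   `lower <= central <= upper`.
#' @export
#' @examples
#' sensitivity_bounds(6977890, "converted",
#'                    consumption_assumption(7.6))
sensitivity_bounds <- function(central,
                               method = c("converted", "reported", "imputed_zero"),
                               assumption = NULL) {
  method <- match.arg(method)
  if (any(central < 0, na.rm = TRUE)) abort("negative central estimate")
  if (method %in% c("reported", "imputed_zero")) {
    return(list(lower = central, upper = central))
  }
  if (is.null(assumption)) {
    abort("converted estimates need the consumption assumption used")
  }
  switch(assumption$mode,
    multiplicative_user_bounds = list(lower = 0.5 * central,
                                      upper = 1.5 * central),
    parameter_ci_bounds = {
      if (is.null(assumption$lower_param)) {
        abort("parameter_ci_bounds mode without CI parameters")
      }
      # users scale as 1/c: higher consumption -> fewer implied users
      list(lower = central * assumption$central / assumption$upper_param,
           upper = central * assumption$central / assumption$lower_param)
    },
    none = list(lower = central, upper = central)
  )
}
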