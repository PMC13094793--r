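# shared numeric helpers

# round half away from zero (base round() is half-to-even)
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# append action messages to a panel's log attribute
log_action <- function(panel, ...) {
  msg <- sprintf(...)
  attr(panel, "log") <- c(attr(panel, "log"), msg)
  panel
}

#' Action log of a disclosure panel
#'
#' Every imputation and reconciliation step appends a human-readable line to
#' the panel's log, so a built series can be audited back to its raw inputs.
#'
#' @param panel A `disclosure_panel`.
#' @return Character vector of logged actions (possibly empty).
#' @export
panel_log <- function(panel) {
  attr(panel, "log") %||% character()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
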