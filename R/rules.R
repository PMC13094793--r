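#' Imputation rules for gaps in the disclosure panel
#'
#' Three documented rule families fill company-years with no usable
#' disclosure:
#' \describe{
#'   \item{launch zero}{pre-launch / pre-disclosure years forced to zero
#'     users (and, implicitly, zero shipments).}
#'   \item{share carry}{a missing shipment volume reconstructed from a known
#'     global stick share `s`: the company's sticks are
#'     `s / (1 - s) * sum(other companies' sticks that year)`, i.e. it holds
#'     share `s` of the global total including itself.}
#'   \item{split carry}{a total-market stick figure rescaled to
#'     domestic-only using the domestic proportion observed in a source
#'     year (requires a `domestic_share` value on the source-year cell).}
#' }
#'
#' @param launch_zero Data frame with columns `company`, `year`.
#' @param share_carry Data frame with columns `company`, `target_year`,
#'   `share` (fraction in (0,1)) and `source_year` (informational).
#' @param split_carry Data frame with columns `company`, `source_year`,
#'   `target_year`.
#' @return An `imputation_rules` object.
#' @export
imputation_rules <- function(launch_zero = NULL, share_carry = NULL,
                             split_carry = NULL) {
  empty <- function(...) tibble::tibble(...)
  launch_zero <- tibble::as_tibble(launch_zero %||%
    empty(company = character(), year = integer()))
  share_carry <- tibble::as_tibble(share_carry %||%
    empty(company = character(), source_year = integer(),
          target_year = integer(), share = double()))
  split_carry <- tibble::as_tibble(split_carry %||%
    empty(company = character(), source_year = integer(),
          target_year = integer()))
  if (nrow(share_carry) &&
      any(share_carry$share <= 0 | share_carry$share >= 1)) {
    abort("share values must lie strictly between 0 and 1")
  }
  structure(list(launch_zero = launch_zero, share_carry = share_carry,
                 split_carry = split_carry),
            class = "imputation_rules")
}

#' Default imputation rules for the packaged disclosure panel
#'
#' Zero users for PMI 2014-2015 (IQOS launched in 2014; Japanese HTP
#' prevalence was 0.2% in 2015 and PMI's first disclosed user base, 2.1M,
#' dates to 2016) and BAT 2016 (glo launched in December 2016). JT's missing
#' 2019-2020 shipments are reconstructed from its known 2019 global stick
#' share of 2.5%. KT&G's unreported 2020 domestic/international split is
#' carried back from the 2021 level; on panels without a `domestic_share`
#' column this rule is a logged no-op.
#'
#' @return An [imputation_rules] object.
#' @export
default_imputation_rules <- function() {
  imputation_rules(
    launch_zero = tibble::tibble(company = c("PMI", "PMI", "BAT"),
                                 year = c(2014L, 2015L, 2016L)),
    share_carry = tibble::tibble(company = "JT", source_year = 2019L,
                                 target_year = c(2019L, 2020L),
                                 share = 0.025),
    split_carry = tibble::tibble(company = "KT&G", source_year = 2021L,
                                 target_year = 2020L)
  )
}

#' Apply imputation rules to a panel
#'
#' Applies launch-zero, then share-carry, then split-carry rules. Every
#' imputed cell is flagged with its rule in the provenance columns, and each
#' action is appended to the panel log. A rule targeting a cell that already
#' holds a value is a conflict unless `override = TRUE`.
#'
#' @param panel A [disclosure_panel].
#' @param rules An [imputation_rules] set; defaults to
#'   [default_imputation_rules()].
#' @param override Allow rules to overwrite non-missing cells.
#' @return The imputed panel.
#' @export
#' @examples
#' panel <- impute_panel(htp_table1())
#' panel_log(panel)
impute_panel <- function(panel, rules = default_imputation_rules(),
                         override = FALSE) {
  stopifnot(inherits(panel, "disclosure_panel"),
            inherits(rules, "imputation_rules"))
  idx <- function(company, year) {
    i <- which(panel$company == company & panel$year == year)
    if (length(i) != 1) {
      abort(sprintf("rule references unknown cell %s %d", company, year))
    }
    i
  }
  for (k in seq_len(nrow(rules$launch_zero))) {
    r <- rules$launch_zero[k, ]
    i <- idx(r$company, r$year)
    if (!override && (!is.na(panel$users[i]) || !is.na(panel$sticks[i]))) {
      abort(sprintf("launch-zero rule conflicts with reported value at %s %d (use override = TRUE)",
                    r$company, r$year))
    }
    panel$users[i] <- 0
    panel$sticks[i] <- 0
    panel$users_source[i] <- "imputed_zero"
    panel$sticks_source[i] <- "imputed_zero"
    panel <- log_action(panel, "launch-zero: %s %d set to 0 users, 0 sticks",
                        r$company, r$year)
  }
  for (k in seq_len(nrow(rules$share_carry))) {
    r <- rules$share_carry[k, ]
    i <- idx(r$company, r$target_year)
    if (!override && !is.na(panel$sticks[i])) {
      abort(sprintf("share-carry rule conflicts with reported sticks at %s %d (use override = TRUE)",
                    r$company, r$target_year))
    }
    others <- panel$sticks[panel$year == r$target_year &
                             panel$company != r$company]
    if (anyNA(others)) {
      abort(sprintf("share-carry for %s %d needs all other companies' sticks that year",
                    r$company, r$target_year))
    }
    panel$sticks[i] <- r$share / (1 - r$share) * sum(others)
    panel$sticks_source[i] <- "imputed_share"
    panel <- log_action(panel,
      "share-carry: %s %d sticks imputed as %.3g (share %.3g of global total, carried from %d)",
      r$company, r$target_year, panel$sticks[i], r$share, r$source_year)
  }
  for (k in seq_len(nrow(rules$split_carry))) {
    r <- rules$split_carry[k, ]
    i <- idx(r$company, r$target_year)
    j <- idx(r$company, r$source_year)
    p <- panel$domestic_share[j]
    if (is.na(p)) {
      panel <- log_action(panel,
        "split-carry: %s %d unchanged (no domestic_share at source year %d)",
        r$company, r$target_year, r$source_year)
      next
    }
    if (is.na(panel$sticks[i])) {
      abort(sprintf("split-carry for %s %d needs a total-market stick figure to rescale",
                    r$company, r$target_year))
    }
    panel$sticks[i] <- panel$sticks[i] * p
    panel$sticks_source[i] <- "imputed_split"
    panel$domestic_only[i] <- TRUE
    panel <- log_action(panel,
      "split-carry: %s %d sticks rescaled to domestic share %.3g of year %d",
      r$company, r$target_year, p, r$source_year)
  }
  panel
}

#' Double-counting reconciliation rule
#'
#' Describes the situation where one manufacturer's published user totals
#' already include another manufacturer's customers outside its home market
#' (under a distribution agreement), so adding the absorbed company's full
#' shipments on top would double-count.
#'
#' @param absorbing Company whose totals subsume the other's international
#'   users.
#' @param absorbed Company restricted to its domestic market.
#' @param from_year First year the rule applies.
#' @param domestic_market_retained Whether the absorbed company keeps a
#'   separately counted domestic contribution (default `TRUE`).
#' @return A `reconciliation_rule`.
#' @export
reconciliation_rule <- function(absorbing, absorbed, from_year,
                                domestic_market_retained = TRUE) {
  if (identical(absorbing, absorbed)) {
    abort("absorbing and absorbed companies must differ")
  }
  structure(list(absorbing = absorbing, absorbed = absorbed,
                 from_year = as.integer(from_year),
                 domestic_market_retained = domestic_market_retained),
            class = "reconciliation_rule")
}

#' Default reconciliation: PMI absorbs KT&G outside South Korea from 2021
#'
#' PMI commercializes KT&G's heated tobacco products outside South Korea
#' under a distribution agreement, and from December 2020 PMI's reported
#' figures include those licensed products. KT&G therefore contributes only
#' its domestic (South Korea) shipments from 2021 onward, and its
#' international volumes are never added on top of PMI's user totals.
#'
#' @return A [reconciliation_rule].
#' @export
default_reconciliation <- function() {
  reconciliation_rule("PMI", "KT&G", 2021L)
}

#' Apply a reconciliation rule to a panel
#'
#' From the rule's effective year onward the absorbed company's cells are
#' flagged `domestic_only`; where a cell carries a `domestic_share`, its
#' sticks are rescaled to the domestic portion. Cells already flagged are
#' left untouched, so the operation is idempotent. The absorbing company's
#' reported user totals are never modified.
#'
#' @param panel A [disclosure_panel].
#' @param rule A [reconciliation_rule]; defaults to
#'   [default_reconciliation()].
#' @return The reconciled panel.
#' @export
reconcile_overlap <- function(panel, rule = default_reconciliation()) {
  stopifnot(inherits(panel, "disclosure_panel"),
            inherits(rule, "reconciliation_rule"))
  years <- attr(panel, "years")
  companies <- attr(panel, "companies")
  if (!all(c(rule$absorbing, rule$absorbed) %in% companies)) {
    abort("reconciliation rule names a company absent from the panel")
  }
  if (length(years) && rule$from_year < min(years)) {
    abort(sprintf("reconciliation effective year %d precedes the panel window (%d-%d)",
                  rule$from_year, min(years), max(years)))
  }
  sel <- which(panel$company == rule$absorbed & panel$year >= rule$from_year &
                 !panel$domestic_only)
  if (!length(sel)) return(panel)
  scale <- !is.na(panel$domestic_share[sel])
  panel$sticks[sel[scale]] <- panel$sticks[sel[scale]] *
    panel$domestic_share[sel[scale]]
  panel$domestic_only[sel] <- TRUE
  log_action(panel,
    "reconciliation: %s restricted to domestic market from %d (absorbed into %s totals internationally; %d cell(s) flagged, %d rescaled)",
    rule$absorbed, rule$from_year, rule$absorbing, length(sel), sum(scale))
}
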