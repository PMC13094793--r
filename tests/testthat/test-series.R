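test_that("default imputation fills every gap of the packaged panel", {
  panel <- impute_panel(htp_table1())

  zero <- function(co, yr) panel[panel$company == co & panel$year == yr, ]
  expect_identical(zero("PMI", 2014)$users, 0)
  expect_identical(zero("PMI", 2014)$users_source, "imputed_zero")
  expect_identical(zero("BAT", 2016)$users, 0)

  # JT 2019: share 2.5% of a global total that includes JT itself
  others_2019 <- (59.7 + 2.5 + 9.0) * 1e9
  jt19 <- zero("JT", 2019)
  expect_equal(jt19$sticks, 0.025 / 0.975 * others_2019)
  expect_identical(jt19$sticks_source, "imputed_share")

  # no unresolved cell remains for the alternative series
  expect_false(anyNA(panel$sticks))
})

test_that("imputation rules refuse to overwrite reported values", {
  rules <- imputation_rules(
    launch_zero = data.frame(company = "PMI", year = 2016))
  expect_error(impute_panel(htp_table1(), rules), "conflict")
  # unless explicitly overridden
  forced <- impute_panel(htp_table1(), rules, override = TRUE)
  expect_identical(forced$users[forced$company == "PMI" &
                                  forced$year == 2016], 0)
  expect_error(imputation_rules(
    share_carry = data.frame(company = "JT", source_year = 2019,
                             target_year = 2019, share = 1.2)),
    "between 0 and 1")
})

test_that("split-carry rescales a total-market figure by the source-year split", {
  records <- data.frame(company = "K", year = 2020:2021,
                        sticks = c(2e9, 3e9),
                        domestic_share = c(NA, 0.6))
  panel <- disclosure_panel(records, companies = "K", years = 2020:2021)
  rules <- imputation_rules(
    split_carry = data.frame(company = "K", source_year = 2021,
                             target_year = 2020))
  out <- impute_panel(panel, rules)
  expect_equal(out$sticks[out$year == 2020], 2e9 * 0.6)
  expect_identical(out$sticks_source[out$year == 2020], "imputed_split")

  # without a domestic share at the source year the rule is a logged no-op
  no_share <- impute_panel(htp_table1())
  expect_match(panel_log(no_share), "split-carry.*unchanged", all = FALSE)
  expect_equal(no_share$sticks[no_share$company == "KT&G" &
                                 no_share$year == 2020], 1.5e9)
})

test_that("reconciliation restricts the absorbed company and is idempotent", {
  panel <- impute_panel(htp_table1())
  once <- reconcile_overlap(panel)
  kt <- once[once$company == "KT&G", ]
  expect_true(all(kt$domestic_only[kt$year >= 2021]))
  expect_false(any(kt$domestic_only[kt$year < 2021]))
  # the absorbing company's reported totals are untouched
  expect_equal(once$users[once$company == "PMI"],
               panel$users[panel$company == "PMI"])

  twice <- reconcile_overlap(once)
  expect_equal(twice$sticks, once$sticks)
  expect_equal(twice$domestic_only, once$domestic_only)

  # a rule effective after the panel end changes nothing
  vac <- reconcile_overlap(panel, reconciliation_rule("PMI", "KT&G", 2030))
  expect_equal(vac$sticks, panel$sticks)
  expect_false(any(vac$domestic_only))
})

test_that("reconciliation scales sticks where a domestic share is known", {
  records <- data.frame(company = c("P", "P", "K", "K"),
                        year = c(2020, 2021, 2020, 2021),
                        users = c(5e6, 6e6, NA, NA),
                        sticks = c(2e10, 2.2e10, 4e9, 5e9),
                        domestic_share = c(NA, NA, NA, 0))
  panel <- disclosure_panel(records, companies = c("P", "K"),
                            years = 2020:2021)
  out <- reconcile_overlap(panel, reconciliation_rule("P", "K", 2021))
  # zero domestic sticks -> the absorbed company contributes 0 users
  expect_equal(out$sticks[out$company == "K" & out$year == 2021], 0)
  expect_error(reconcile_overlap(panel, reconciliation_rule("P", "K", 2010)),
               "precedes")
  expect_error(reconciliation_rule("P", "P", 2021), "differ")
})

test_that("primary series reproduces the 2024 headline from the fixture", {
  series <- build_primary_series(table1_resolved())
  y24 <- series[series$year == 2024, ]
  conv24 <- 8.3e9 / (12 * 365) + 14.1e9 / (7.6 * 365)
  expect_equal(y24$total_central, 42.4e6 + conv24)
  expect_equal(y24$total_lower, 42.4e6 + 0.5 * conv24)
  expect_equal(y24$total_upper, 42.4e6 + 1.5 * conv24)

  # centrals are non-decreasing across 2014-2024
  expect_true(all(diff(series$total_central) >= 0))
})

test_that("primary series resolves cells by method with exact additivity", {
  series <- build_primary_series(table1_resolved())
  comp <- company_breakdown(series)
  p24 <- comp[comp$company == "PMI" & comp$year == 2024, ]
  expect_identical(p24$method, "reported")
  expect_equal(p24$central, 32.2e6)
  expect_equal(p24$lower, p24$central)

  k24 <- comp[comp$company == "KT&G" & comp$year == 2024, ]
  expect_identical(k24$method, "converted")
  expect_equal(round(k24$central), 1894977)

  expect_identical(comp$method[comp$company == "PMI" & comp$year == 2014],
                   "imputed_zero")

  by_year <- aggregate(cbind(central, lower, upper) ~ year, comp, sum)
  expect_equal(by_year$central, series$total_central)
  expect_equal(by_year$lower, series$total_lower)
  expect_equal(by_year$upper, series$total_upper)
})

test_that("all-reported panels have bounds equal to centrals", {
  series <- build_primary_series(all_reported_panel(),
                                 assumptions = list())
  expect_equal(series$total_lower, series$total_central)
  expect_equal(series$total_upper, series$total_central)
})

test_that("unresolvable cells are hard coverage errors", {
  panel <- disclosure_panel(data.frame(company = "A", year = 2020),
                            companies = "A", years = 2020)
  expect_error(build_primary_series(panel, assumptions = list()),
               "coverage error")
  # sticks without an assumption for that company is also a coverage failure
  panel2 <- disclosure_panel(data.frame(company = "A", year = 2020,
                                        sticks = 1e9),
                             companies = "A", years = 2020)
  expect_error(build_primary_series(panel2, assumptions = list()),
               "no consumption assumption")
})

test_that("alternative series converts all shipments at the common parameter", {
  series <- build_alternative_series(table1_resolved())
  y24 <- series[series$year == 2024, ]
  total24 <- (139.7 + 8.3 + 21.0 + 14.1) * 1e9
  expect_equal(y24$total_central, total24 / (7.3 * 365))
  expect_equal(y24$total_lower, total24 / (8.27 * 365))
  expect_equal(y24$total_upper, total24 / (6.33 * 365))

  # zero-shipment years contribute exactly zero with zero bounds
  y14 <- series[series$year == 2014, ]
  expect_equal(c(y14$total_central, y14$total_lower, y14$total_upper),
               c(0, 0, 0))

  # the shipment-only total exceeds the mixed series in 2024 on this fixture
  primary24 <- build_primary_series(table1_resolved())$total_central[11]
  expect_gt(y24$total_central, primary24)
})

test_that("alternative series is invariant to any reported user count", {
  panel <- table1_resolved()
  base <- build_alternative_series(panel)
  perturbed <- panel
  idx <- which(!is.na(perturbed$users) & perturbed$users > 0)
  perturbed$users[idx] <- perturbed$users[idx] * 3 + 1e5
  expect_identical(build_alternative_series(perturbed)$total_central,
                   base$total_central)
  expect_identical(build_alternative_series(perturbed)$total_upper,
                   base$total_upper)

  # but missing sticks anywhere are a coverage error
  broken <- panel
  broken$sticks[1] <- NA
  expect_error(build_alternative_series(broken), "coverage error")
})

test_that("series totals are additive for random panels", {
  for (seed in 1:10) {
    panel <- random_panel(seed)
    panel$sticks[is.na(panel$sticks)] <- 0
    a <- consumption_assumption(8)
    series <- build_primary_series(panel, assumptions = list(A = a, B = a, C = a))
    comp <- company_breakdown(series)
    by_year <- aggregate(cbind(central, lower, upper) ~ year, comp, sum)
    expect_equal(by_year$central, series$total_central)
    expect_equal(by_year$lower, series$total_lower)
    expect_equal(by_year$upper, series$total_upper)
  }
})

test_that("empty series yields an empty breakdown", {
  series <- htp_series(tibble::tibble(company = character(), year = integer(),
                                      central = double(), lower = double(),
                                      upper = double(), method = character()),
                       variant = "primary")
  expect_equal(nrow(company_breakdown(series)), 0)
  expect_equal(nrow(series), 0)
})

test_that("series round-trip to CSV preserves totals", {
  series <- build_primary_series(table1_resolved())
  path <- withr::local_tempfile(fileext = ".csv")
  write_series(series, path, json = TRUE)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$total_central, series$total_central)
  expect_true(file.exists(sub("\\.csv$", "_companies.csv", path)))
  expect_true(file.exists(sub("\\.csv$", ".json", path)))
})
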