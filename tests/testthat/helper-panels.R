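# fixtures built in code for unit and property tests

# a small panel written to a temp CSV and loaded through read_panel()
write_temp_panel <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c("company,brand,year,users_millions,sticks_billions,report_vintage,notes",
               lines), path)
  path
}

# random panel in canonical units with a random missingness pattern
random_panel <- function(seed, companies = c("A", "B", "C"),
                         years = 2018:2022) {
  withr::with_seed(seed, {
    grid <- expand.grid(company = companies, year = years,
                        stringsAsFactors = FALSE)
    grid$users <- ifelse(runif(nrow(grid)) < 0.4, NA_real_,
                         round(runif(nrow(grid), 0, 30), 1) * 1e6)
    grid$sticks <- ifelse(runif(nrow(grid)) < 0.4, NA_real_,
                          round(runif(nrow(grid), 0, 150), 1) * 1e9)
    disclosure_panel(grid, companies = companies, years = years)
  })
}

# fully resolved panel: every cell carries both users and sticks
all_reported_panel <- function(seed = 42, companies = c("A", "B"),
                               years = 2020:2023) {
  withr::with_seed(seed, {
    grid <- expand.grid(company = companies, year = years,
                        stringsAsFactors = FALSE)
    grid$users <- round(runif(nrow(grid), 1, 30), 1) * 1e6
    grid$sticks <- grid$users * 8 * 365
    disclosure_panel(grid, companies = companies, years = years)
  })
}

table1_resolved <- function() {
  reconcile_overlap(impute_panel(htp_table1()))
}
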