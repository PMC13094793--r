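Package: heatcount
Title: Global Heated Tobacco Product User Estimation from Manufacturer Disclosures
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds annual global time series of heated tobacco product (HTP)
    user estimates for 2014-2024 from manufacturer disclosure panels. A primary
    series combines company-reported user counts with stick-shipment conversions
    under brand-specific daily-consumption assumptions and +/-50% sensitivity
    bounds; an alternative series converts all shipments with a common
    literature-based consumption parameter (7.3 sticks/day, 95% CI 6.33-8.27);
    a complementary estimator aggregates nationally representative survey
    prevalence into country user counts. Includes panel validation and
    inventory, vintage selection, imputation and double-counting reconciliation
    rules, consumption-parameter calibration from dual-disclosure years, and a
    synthetic market generator with known ground truth for parameter- and
    user-recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
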