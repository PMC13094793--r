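---
title: "Estimating global heated tobacco product users from manufacturer disclosures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating global heated tobacco product users from manufacturer disclosures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatcount)
```

## The estimation problem

Heated tobacco products (HTPs) — devices that heat a manufactured tobacco
stick to around 250–350 °C instead of burning it — went from commercial
launch in 2014 to a major segment of the global nicotine market, yet no
harmonized survey-based count of their users exists: most national tobacco
surveys still lack HTP questions, and where they exist the definitions
vary. What *is* published, annually and globally, are manufacturer
disclosures: user counts for some companies and years, and heated-tobacco
stick shipment volumes for most. Because the market is concentrated in four
firms (PMI/IQOS, BAT/glo, JT/Ploom, KT&G/lil), those disclosures support a
global annual time series.

The package builds that series three ways:

1. **Primary series** — use a company's reported user count when one
   exists; otherwise convert its shipments to implied users with a
   brand-specific daily-consumption assumption, and carry a ±50%
   sensitivity band on every converted component.
2. **Alternative (shipment-only) series** — ignore all reported user
   counts, which differ in definition across firms, and convert every
   company's shipments with a single literature-based consumption
   parameter and its 95% CI.
3. **Survey series** — multiply nationally representative current-use
   prevalence by the matching cohort population, country by country, and
   aggregate. With 35 surveyed countries out of 70+ markets this is a
   conservative lower bound, not a competing global total.

## The conversion model

The core estimator is deliberately simple:

$$\mathrm{Users}_y \;=\; \frac{\mathrm{sticks}_y}{c \times 365},$$

where $\mathrm{sticks}_y$ is the year's shipment volume (stick units) and
$c$ the mean number of sticks a user consumes per day. The year length is
fixed at exactly 365 days; leap years are ignored, consistent with how the
conversion is used in practice and far below the other uncertainties. The
conversion is exact and real-valued; rounding happens only at reporting.

Two immediate consequences that the test-suite asserts as properties:
scaling shipments by $k$ scales users by $k$, and mis-stating $c$ by a
factor $f$ scales every converted estimate by exactly $1/f$. The inverse
statistic, *implied daily consumption* $\mathrm{sticks}/(\mathrm{users}
\times 365)$, is defined whenever a company-year discloses both quantities.

### Calibrating the brand parameters

Two companies never (KT&G) or rarely (JT) publish user counts, so their
$c$ must come from elsewhere. `calibrate_consumption()` computes the
implied daily consumption for every *dual-disclosure* year of a donor
company — both values published and strictly positive — and averages the
per-year ratios:

* donor **PMI** (nine dual years), mean 11.99, rounded to the integer
  → **12 sticks/day**, applied to KT&G;
* donor **BAT** (six dual years), mean 7.64, rounded to one decimal
  → **7.6 sticks/day**, applied to BAT's own missing years and to JT.

The arithmetic mean of per-year ratios is used rather than the ratio of
sums: each disclosure year then carries equal weight regardless of market
size, and it is the only reading that reproduces the published parameters
(the ratio of sums over BAT's dual years gives ≈7.40, not 7.6). The
donor-specific rounding precision (integer vs one decimal) is part of the
assumptions config. A single dual-disclosure year calibrates to that year's
own ratio, and converting that year's shipments back recovers its reported
users to rounding precision — a round-trip the tests exercise.

### Sensitivity bounds

Directly reported user counts carry **no** sensitivity: their lower and
upper bounds equal the central value. For converted components two bound
modes exist:

* `multiplicative_user_bounds` — the ±50% band is applied to the converted
  *user count* (×0.5, ×1.5). This is the primary-series convention. The
  alternative reading — perturbing the consumption *parameter* by ±50% —
  would give asymmetric user bounds (×2/3, ×2) and cannot produce the
  near-symmetric published range around the 2024 primary total; the
  user-space reading does, which is why it is the default. Both modes are
  implemented.
* `parameter_ci_bounds` — bounds re-run the conversion at the endpoints of
  a consumption CI, so the *upper* consumption endpoint yields the *lower*
  user bound and vice versa. The shipment-only series uses this mode with
  the literature parameter 7.3 sticks/day (95% CI 6.33–8.27), a mean
  reported by current users in German surveys 2018–2023 and consistent
  with Italian estimates (7.9).

A useful consequence of user-space ±50% bounds: if the true consumption is
mis-specified by any factor $f \in [0.5, 1.5]$, the interval around the
converted estimate still contains the truth (the estimate is
$\mathrm{truth}/f$ and the band spans $[0.5, 1.5] \times \mathrm{truth}/f$).
The synthetic-recovery tests verify this band exactly.

## Panel handling

The disclosure panel is rectangular — all 4 × 11 = 44 company-year cells
are materialized even for pre-launch years — so inventory denominators
never drift. Internal units are persons and stick units; millions/billions
exist only in the CSV dialect. An explicit `0.0` in the input is a
*reported* value, not a gap: this matters for the inventory (the packaged
panel classifies as 25 users-reported / 14 sticks-only / 5 neither) and for
launch years, where zero users is a substantive statement.

**Vintages.** Manufacturers revise historical figures; when several
disclosures of one company-year exist, the latest `report_vintage` wins and
undated records lose to dated ones. Two records sharing the maximal vintage
but disagreeing on values raise an error rather than a silent pick — the
latest-vintage rule provides no tiebreak, so silence would hide a data
problem.

**Imputation.** Three rule families cover the five cells with neither
value:

* *Launch zeros*: PMI 2014–2015 and BAT 2016. The BAT zero reflects glo's
  December 2016 launch. PMI 2014 reflects a launch-year user base too small
  to measure (Japanese HTP prevalence was 0.2% in 2015); 2015 is treated
  the same way since PMI's first disclosed user base — already 2.1 million
  — dates to 2016 and no earlier disclosure exists.
* *Share carry*: JT's missing 2019–2020 shipments are reconstructed from
  its known 2019 global stick share of 2.5%. If JT holds share $s$ of a
  global total that includes JT, its sticks are
  $s/(1-s)\times\sum(\text{other companies' sticks})$. Note the panel
  prints explicit zeros for JT 2017–2018, so the rule applies only to
  2019–2020; the action log records each application.
* *Split carry*: KT&G's 2020 domestic/international split is carried back
  from the 2021 level. This needs a `domestic_share` value on the source
  year; the packaged panel's KT&G 2021+ stick values are already
  domestic-only, so on that fixture the rule is a logged no-op. It remains
  implemented (and tested on synthetic panels) for inputs that supply a
  total-market 2020 figure plus a 2021 share.

Rules never overwrite a reported value unless explicitly overridden, and a
company-year that resolves to neither a reported value, a conversion, nor a
rule is a hard coverage error — never a silent zero.

**Double-counting reconciliation.** PMI distributes KT&G's products
outside South Korea and, from December 2020, includes them in its own
reported figures. From 2021 onward KT&G therefore contributes only its
domestic shipments, and its international volumes are never added on top of
PMI's totals. `reconcile_overlap()` flags the absorbed cells
`domestic_only` (rescaling by `domestic_share` where one is known) and is
idempotent, so accidentally applying it twice cannot double-shrink.

## Survey aggregation

`users_from_prevalence()` computes
$\mathrm{round}(\mathrm{prevalence}/100 \times \mathrm{population})$,
rounding to the nearest person with ties half away from zero. The
aggregate, however, sums the *printed* user column of the source table,
keeping the recomputed value as a cross-check column: several printed cells
were evidently computed from unrounded population denominators, and one —
Uzbekistan — from an unrounded *prevalence* (the printed 0.24% is a
display rounding of ≈0.235%, so recomputation lands about a thousand
persons high on a 21.5-million denominator). All other 34 countries
recompute to within ±5 persons. No age-standardization or survey-year
alignment is attempted; cohort and year travel as metadata only.

Top-contributor shares rank countries by users, descending, with ties
broken by country label so the ranking is deterministic.

## The synthetic market generator

`market_scenario()` + `generate_market()` produce panels with known ground
truth so every pipeline stage is testable without external data. Each
company's true user base follows logistic uptake
$K/(1+e^{-r(t-t_0)})$ from its launch year (zero before) — the simplest
monotone curve with saturation, matching the observed pattern of near-zero
launch years followed by rapid then slowing growth. True shipments are
definitionally $\mathrm{users}\times c\times 365$, optionally perturbed by
multiplicative lognormal noise on the shipment channel only (default
$\sigma = 0.05$, about ±5% reporting noise; user counts are definitional
truth). A disclosure mask (`both` / `users_only` / `sticks_only` / `none`)
then emulates selective disclosure, and display rounding — users to 0.1
million, sticks to 0.1 billion — emulates how figures are printed, which is
exactly the resolution limit that keeps headline reproduction from being
exact on the real panel.

What the generator does *not* emulate: user churn and dual use, device
generations with different consumption, within-year seasonality, price
effects, and cross-company definitional differences in what a "user" is.
Passing recovery tests therefore show the estimator is correct *given its
model*, not that manufacturer definitions are comparable — which is
precisely why the shipment-only alternative series exists.

Generation is a pure function of the scenario (seed included) and restores
the caller's RNG state.

## Numerical choices and degenerate inputs

* Year length 365 exactly; no leap-year adjustment.
* All internal arithmetic is unrounded; headline totals are conventionally
  reported at 0.1 million.
* Display/report rounding uses half-away-from-zero (the convention of the
  source tables), not banker's rounding.
* Zero shipments convert to zero users with zero-width bounds; zero users
  make implied consumption undefined (error, not `Inf`).
* An empty input file yields an empty panel; an empty series yields an
  empty breakdown.
* Relative recovery error is defined as 0 when truth and estimate are both
  zero (pre-launch years).

## Problem sizes

The packaged panel is 44 cells and the survey table 35 rows, so the full
pipeline runs in well under a second. Property-style tests loop over 10–25
randomized cases per invariant under fixed seeds; synthetic-recovery tests
use two-company, 11-year markets. These sizes were chosen because the
estimators are closed-form — larger simulations would add runtime without
adding information.

## Limitations

All limitations of the source data flow through: company user definitions
differ (PMI's 7-day-use definition vs BAT's undefined "consumer" counts);
display-rounded inputs mean published headline totals are reproducible only
to a few percent (the package's tolerance checks use ±3%); consumption
truly varies by market, device generation and user profile, which the ±50%
band approximates but does not model; and the survey series inherits each
survey's cohort and wording. The package estimates how many people use
HTPs; it cannot say whether that use displaces or supplements cigarette
smoking.
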