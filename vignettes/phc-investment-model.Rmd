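---
title: "Methods: projecting primary health care investment needs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting primary health care investment needs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phcguideposts)
```

## The model in one paragraph

`phcguideposts` projects what it would cost low- and middle-income countries
to scale up primary health care (PHC) between 2020 and 2030, and what that
scale-up would buy in health. PHC is represented by three nested *measures*
of scope: measure 1 is the preventive/outpatient core, measure 2 adds
general inpatient care and full system support, and measure 3 adds
cross-sectoral investments (water and sanitation, food safety, and related
services). Costs are built with an ingredients approach — every line is a
quantity per year multiplied by a price — and are incremental to a
*flatline* counterfactual in which intervention coverage never moves from
its baseline. Impact is projected with a coverage-effectiveness model and
converted to life-expectancy gains through abridged period life tables and
to healthy life-years through disability weights. A financing module asks
whether projected health spending could absorb the incremental cost under a
business-as-usual trend and under +1 and +2 percentage-point-of-GDP paths.

The country inputs behind the original 67-country analysis are not public,
so the package ships a seeded generator that emulates the cohort's
structure. Everything downstream consumes either generated or user-supplied
country profiles with the same schema.

## Measures and allocation rules

The catalog marks each of 188 interventions as belonging to measure 1
(143 interventions), measure 2 (152) and/or measure 3 (160), with
membership nested by construction (`m1 ⊆ m2 ⊆ m3`). Shared health-system
costs attach to a measure through `measure_spec()`:

| rule | m1 | m2 | m3 |
|---|---|---|---|
| health centres | 100% | 100% | 100% |
| district hospitals | 33% | 81% | 81% |
| provincial hospitals | 3% | 27% | 27% |
| governance, financing | 80% | 100% | 100% |
| information systems | facility-based | full sector | + census/civil registry |
| emergency preparedness | laboratory share | full | full |
| cash transfers | none | birth-related | general |
| cross-sectoral envelope | no | no | yes |
| supply chain | commodity-cost ratio of the measure | idem | idem |
| cold chain | 100% | 100% | 100% |

The hospital shares reflect health-accounts data on the non-specialised
share of care at each level; the jump from 33%/3% to 81%/27% is what
"adding general inpatient care" means in accounting terms. The
intervention list itself is not public: the packaged catalog is synthetic,
preserving the printed counts, the platform taxonomy and the named example
interventions (vaccination, family planning, first-line tuberculosis
treatment under measure 1; normal delivery and basic emergency obstetric
care entering at measure 2; water and sanitation at measure 3). Users can
replace any column or the whole table; `validate_catalog()` enforces the
range and nesting invariants.

## Coverage trajectories

Coverage holds at its baseline through 2019 (the framework assumes little
progress over 2015-19) and then climbs linearly to a 2030 target that
depends on health-system maturity: 0.70 (conflict), 0.80 (vulnerable),
0.85/0.90/0.95 (system strength 1/2/3). The functional form and the
endpoints are not published; linear paths with these config-exposed targets
are this package's choice. Coverage is never scaled down — a baseline above
its target stays where it is — which makes the scale-up trajectory dominate
the flatline everywhere and keeps every incremental quantity non-negative.

```{r}
build_trajectory(0.25, "hs1")$coverage
```

## The cost engine

`cost_country()` produces a country-year-component ledger of capital and
recurrent incremental costs, 2020-2030, in constant US$2014. All reference
prices are scaled by the country's unit price index, so costs are
homogeneous of degree one in prices, and every component is proportional to
some increment of the scale-up, so zero scale-up means a zero ledger.

* **Commodities.** Persons reached (population × target fraction × in-need
  fraction × coverage) × units per case × price, minus the flatline amount.
  An intervention's `capital_share` routes part of this to equipment.
* **Workforce.** Incremental service minutes (visits × minutes per visit
  over the measure's interventions, scale-up minus flatline) divided by
  99 000 minutes per worker-year, times a reference salary of $10 000.
  The *guide post* for workers per 1000 population instead follows the
  density-target route: the measure's share of bottom-up minutes within the
  full package, applied to the 8.9-per-1000 target workforce, floored at
  the current density (the model never sheds existing workers). The
  bottom-up route prices the increment because it is the definition under
  which both engine invariants — zero increment at zero scale-up, and cost
  monotonicity across nested measures — hold exactly.
* **Infrastructure and equipment.** Facility capital is a per-capita
  reference ($250/$220/$180 per unit of mean coverage gain for health
  centres, district and provincial hospitals; equipment $80/$70/$60)
  spread over a 2016-2030 build-out, with the measure's level shares
  applied. Capital modelled for 2016-19 is then redistributed uniformly
  into 2020-30 (`redistribute_capital()`), conserving the total exactly;
  the uniform schedule is this package's choice, as only the fact of the
  redistribution is published. Maintenance accrues as 25% of the annual
  capital flow.
* **Shared components.** Supply chain, cold chain, information systems,
  governance, financing, emergency preparedness, cash transfers and the
  cross-sectoral envelope are per-capita reference amounts scaled by the
  year's mean coverage increment and then scoped by the measure rules
  above. The supply-chain share is the ratio of the measure's commodity
  cost to the full-package commodity cost, recomputed per year.
* **Programme support** is a 10% markup on direct intervention costs
  (commodities plus incremental workforce); the published model includes it
  "in its entirety" without printing a rate, so the rate is config-exposed.

Accounting identities (component sums equal grand totals, grouped totals
re-sum) are exact up to a 1e-6 relative tolerance used in tests.

## Impact

The disease-specific engines of the parent tool (OneHealth) are not
reproducible from published material. The package's declared stand-in:
each intervention carries an `effectiveness` — the fraction of its cause
group's deaths averted at full incremental coverage — and interventions on
the same cause combine on the residual,

$$f_c = 1 - \prod_{i \in c} \bigl(1 - e_i\,\Delta p_i\bigr),$$

so combined aversion saturates instead of exceeding the deaths at risk.
Default effectivenesses are small (beta(1.5, 20), mean ≈ 0.07) because
each intervention addresses a narrow slice of its cause group; with ~20
interventions per cause this yields cause-level averted fractions in the
10-40% range on typical synthetic countries. Impact magnitudes are
therefore structural, not calibrated: signs, orderings (more coverage, more
effectiveness, broader measures ⇒ more deaths averted) and identities
(neonatal + post-neonatal = under-5 exactly) are the meaningful outputs.

Life expectancy uses standard abridged period life tables
(`build_life_table()`): `qx = n·mx / (1 + (n − ax)·mx)` capped at one, a
radix of 100 000, `Lx = n·lx − (n − ax)·dx`, and `Lx = lx/mx` in the open
interval. Separation factors default to half the interval width, 0.3 years
for the infant interval — standard demographic practice, unspecified in the
source. Averted deaths in 2030 convert to rate reductions through the age
group's mid-year person-years; tuberculosis, NTD and cervical-cancer
aversions are subtracted from the 2030 death counts through a dedicated
adjustment path, mirroring how those areas are computed outside the main
tool. Constant-hazard tables reproduce the exponential closed form
(e0 = 1/h) within 0.5 years across hazards 0.001-0.1 on single-year ages.

Healthy life-years combine (i) person-years of survivors gained from
averted deaths and stillbirths, valued at the remaining *healthy* life
expectancy (life-table expectancy × (1 − 0.1 average disability), truncated
at the 2030 horizon end, mid-year convention) and (ii) a morbidity term
crediting persons effectively treated in a year with their state's
disability weight for that year. Weights live in an editable reference
table (`inst/extdata/disability_weights.tsv`).

## Financing

Business-as-usual extrapolates each country's historical health expenditure
share of GDP by ordinary least squares on at least three annual points,
clamped to 1-25% to keep degenerate trends finite. The +1/+2 point
scenarios interpolate linearly from the 2019 level to +1 or +2 percentage
points of GDP in 2030 and are applied as *floors* over the
business-as-usual path: a country whose own trend already beats the floor
keeps its trend. This floor reading is a deliberate design choice — it is
what makes incremental funds rise monotonically across scenarios for every
country, and hence gap-country counts fall monotonically from
business-as-usual to the +2 scenario, which the scenario logic is meant to
express. The funding gap is
`max(0, incremental PHC cost − allocation × incremental funds)` with the
allocation share defaulting to 1 (every incremental health dollar countable
against PHC) because the original allocation rule is in unpublished
appendix material; the default is generous and prominently config-exposed.
Gap counts compare 2030 costs with 2030 funds.

## The synthetic cohort

`generate_countries()` emulates the study's 67 LMICs: a 0.33/0.45/0.22
income mix, maturity uniform within income group (the true composition is
unpublished), and income-graded draws for every field. Anchors printed in
the source are used directly: current recurrent PHC spending per capita of
$25/$34/$304 by income group, workforce densities of 1.4/4.6/7.9 per 1000,
baseline outpatient visits near 1.7/1.7/5.2 per capita, and health
expenditure around 5.6% of GDP. The remaining levels — log-normal GDP per
capita around $700/$2200/$7500, populations around 15-40 million, price
indices around 0.55/1.0/1.7, beta-distributed baseline coverage with
maturity-specific means (0.25 in conflict settings up to 0.62 in the
strongest systems) plus an income offset, and a mortality schedule with a
separate under-5 level and a Gompertz-type adult slope per income group —
were chosen once as realistic LMIC values and are config-exposed, not
revisited. The expenditure history is a linear trend plus small noise so
the trend extrapolation is well defined.

What the generator does *not* emulate: real age-pyramid dynamics (cohort
flow, migration), within-country heterogeneity, correlated intervention
coverage, epidemiological transition over the projection window, and the
actual country list. Passing tests therefore demonstrate that the
machinery is correct and its invariants hold under realistic structure —
not that the numeric outputs match any real country, and headline dollar
and death totals are expected to differ from the published ones, which
depend on the restricted inputs.

## Numerical choices and degenerate inputs

* Sums are compared at 1e-6 relative tolerance; internal arithmetic is
  unrounded, display rounding (integer percent, half-up) happens only in
  reporting operations.
* Coverage, averted fractions and gaps are floored at zero rather than
  allowed to go negative; coverage decreases in impact inputs warn and
  contribute zero.
* A measure whose minutes denominator is zero gets a zero workforce share;
  a zero commodity denominator gives a zero supply-chain ratio.
* Per-capita group aggregates weight countries by their 2020 population
  (first investment year); the weight year is configurable since the
  published choice is unstated.
* Capital redistribution spreads uniformly over the 11 receiving years.

## Problem sizes

The default pipeline (67 countries × 188 interventions × 3 measures × 3
scenarios) completes in well under a minute on one core; the test suite
exercises the same code paths on 2-9-country cohorts with 10-60-item
catalogs, plus one full-scale run to verify cohort-level behaviour and a
600-country draw to check the generator's income-gradient orderings.

## Known limitations

* Impact magnitudes come from a declared stand-in, not the original
  disease models; treat them as structural.
* Current PHC expenditure is consumed as an input (health-accounts,
  recurrent-only), never estimated from raw expenditure data.
* No efficiency or reallocation modelling (shifting tertiary care towards
  PHC lowers net cost in reality; the model keeps them additive).
* Cross-sectoral deaths averted are limited to the water-sanitation route;
  other cross-sectoral benefits are costed but not credited with impact.
* The financing module does not decompose revenue sources (domestic versus
  donor) or model debt and taxation.
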