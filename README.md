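# phcguideposts

Investment guide posts for primary health care (PHC) in low- and
middle-income countries: an ingredients-based projection of what scaling up
PHC between 2020 and 2030 costs, what it buys in deaths averted, life
expectancy and healthy life-years, and whether projected health spending
can pay for it.

The package is aimed at health-economic modellers and health-financing
analysts. It reimplements, as tested and reusable R code, a projection
framework in which PHC is defined by three *nested measures* of scope —

* **Measure 1** — preventive and outpatient care (143 of 188 modelled
  interventions) with partial system support (33%/3% of district/provincial
  hospital costs, 80% of governance and financing);
* **Measure 2** — adds general inpatient care (152 interventions; hospital
  shares rise to 81%/27%, system support to 100%);
* **Measure 3** — adds cross-sectoral investment such as water and
  sanitation (160 interventions);

— and every cost line is a quantity multiplied by a price:

```
cost(c, y) = Σ_i  pop(c, y) · target_i · need_i · Δcoverage_i(y) · units_i · price_i · index_c
           + Δminutes(c, y) / minutes_per_FTE · salary_c
           + facility, equipment, and shared-system envelopes scoped per measure
```

Incremental costs are measured against a **flatline** counterfactual
(coverage frozen at baseline). Coverage rises linearly after 2019 to a 2030
target graded by health-system maturity (0.70 for conflict settings up to
0.95 for the strongest systems). Impact converts coverage gains into deaths
averted via a residual-combination coverage-effectiveness model, into
life-expectancy gains via abridged period life tables (mx → qx → lx → Lx →
Tx → ex), and into healthy life-years via disability weights. Financing
projects health expenditure as a share of GDP under business-as-usual and
+1/+2 percentage-point scenarios and counts countries whose incremental PHC
cost exceeds their incremental funds.

The original 67-country input set is not public, so a seeded generator
(`generate_countries()`) emulates its structure — three income groups
crossed with five system-maturity categories, income-graded prices,
coverage, workforce and mortality. All headline magnitudes on synthetic
countries are structural illustrations, not reproductions of published
totals; the arithmetic identities and invariants of the framework are the
tested surface. See the methods vignette
(`vignettes/phc-investment-model.Rmd`) for the model, parameter defaults
and design choices.

## Worked example

Cost, impact and financing for one synthetic country:

```r
library(phcguideposts)

catalog   <- generate_catalog(seed = 1)                       # 188 interventions
countries <- generate_countries(generator_config(n_countries = 10, seed = 1),
                                catalog = catalog)
co  <- countries[[1]]                                         # lower-middle, hs3
led <- cost_country(co, catalog, "m1")                        # ledger 2020-2030
sum(led$amount) / 11 / population_total(co, 2020)             # per capita per year
#> 34.65
aggregate_costs(led, component)                               # largest components:
#> infrastructure 3.43e9, equipment 1.04e9, workforce 7.09e8, commodities 6.38e8

im <- impact_country(co, catalog, "m1")
sum(im$totals$deaths_averted)                                 # deaths averted 2020-30
#> 1440186
im$le$gain_vs_2015                                            # life expectancy, years
#> 5.46

funding_gap(project_che(co, "progress1"), led, 2030)          # 2030 gap, US$
#> 0
```

Read: scaling up the outpatient/preventive core in this 19-million-person
country costs an additional $34.65 per person per year on average over
2020-30 (dominated by facility infrastructure), averts about 1.44 million
deaths over the period, raises life expectancy at birth by 5.5 years by
2030, and is fully fundable in 2030 if health spending rises one
percentage point of GDP.

The cohort-scale analysis lives in `analysis/01_simulate.R` …
`analysis/05_report.R`, thin drivers over the package that write their
tables under `results/`; `run_pipeline()` executes the same stages in one
call.

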