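# Hand-built fixtures: a tiny catalog and fully deterministic country
# profiles with round numbers, so tests can compute expected values by
# direct arithmetic.

tiny_catalog <- function() {
  tibble::tibble(
    intervention_id = c("T1", "T2"),
    name = c("Outpatient treatment A", "Outpatient treatment B"),
    platform = c("first_level_clinical", "first_level_clinical"),
    m1 = TRUE, m2 = TRUE, m3 = TRUE,
    target_pop_fraction = c(0.5, 0.2),
    in_need_fraction = c(0.4, 0.5),
    units_per_case = c(2, 1),
    commodity_price = c(3, 10),
    visits_per_case = c(2, 1),
    minutes_per_visit = c(30, 20),
    capital_share = c(0, 0),
    effectiveness = c(0.1, 0.2),
    cause_group = c("ncd", "tb")
  )
}

# A country with flat population, unit price index 1 and hand-set scalars.
# Mortality is a single flat hazard on the "other" cause unless a custom
# mortality table is supplied.
make_test_country <- function(id = "X01", pop_total = 1e6, maturity = "hs1",
                              baselines = c(T1 = 0.25, T2 = 0.45),
                              income_group = "low", mx_flat = 0.02,
                              gdp_pc = 1000, che_hist = rep(5, 5),
                              price_index = 1, growth = 0,
                              mortality = NULL) {
  ages <- phc_age_groups()
  years <- phc_years()
  pop_tab <- tidyr::expand_grid(year = years, age_group = ages$age_group,
                                sex = c("female", "male"))
  pop_tab$pop <- pop_total * (1 + growth)^(pop_tab$year - 2015) /
    (2 * nrow(ages))
  if (is.null(mortality)) {
    mortality <- tidyr::expand_grid(age_group = ages$age_group,
                                    sex = c("female", "male"))
    mortality$cause_group <- "other"
    mortality$mx <- mx_flat
  }
  structure(list(
    country_id = id,
    income_group = income_group,
    maturity = maturity,
    population = pop_tab,
    gdp_per_capita = tibble::tibble(year = years, gdp_pc = gdp_pc),
    che_pct_gdp = tibble::tibble(year = 2015:2019, che_pct = che_hist),
    current_phc_exp_per_capita = 25,
    workforce_density = c(doctor = 0.3, nurse_midwife = 0.9, other = 0.8),
    baseline_visits_per_capita = 1.7,
    baseline_coverage = tibble::tibble(intervention_id = names(baselines),
                                       coverage = unname(baselines)),
    mortality_rate = mortality,
    unit_price_index = price_index
  ), class = "country_profile")
}

small_cohort <- function(n = 6, seed = 11) {
  cat <- generate_catalog(40, seed = seed, m_counts = c(28, 33, 36))
  list(catalog = cat,
       countries = generate_countries(
         generator_config(n_countries = n, seed = seed, n_interventions = 40),
         catalog = cat))
}
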