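# Generator contracts: counts, determinism, invariants, income gradients.

test_that("generator returns the requested number of valid profiles", {
  cfg <- generator_config(n_countries = 9, seed = 3, n_interventions = 20)
  cat <- generate_catalog(20, seed = 3, m_counts = c(12, 15, 17))
  countries <- generate_countries(cfg, catalog = cat)
  expect_length(countries, 9)
  for (co in countries) {
    expect_s3_class(co, "country_profile")
    expect_identical(nrow(validate_country_profile(co)), 0L)
    expect_setequal(unique(co$population$year), phc_years())
    expect_gte(nrow(co$che_pct_gdp), 5)
  }
})

test_that("identical configuration yields bit-identical profiles", {
  cfg <- generator_config(n_countries = 5, seed = 99, n_interventions = 15)
  cat <- generate_catalog(15, seed = 99, m_counts = c(8, 10, 12))
  a <- generate_countries(cfg, catalog = cat)
  b <- generate_countries(cfg, catalog = cat)
  expect_identical(a, b)
})

test_that("different seeds yield different cohorts", {
  cat <- generate_catalog(15, seed = 1, m_counts = c(8, 10, 12))
  a <- generate_countries(generator_config(5, seed = 1, n_interventions = 15),
                          catalog = cat)
  b <- generate_countries(generator_config(5, seed = 2, n_interventions = 15),
                          catalog = cat)
  expect_false(identical(a, b))
})

test_that("income gradients hold on group means at large n", {
  cfg <- generator_config(n_countries = 600, seed = 17, n_interventions = 10)
  cat <- generate_catalog(10, seed = 17, m_counts = c(6, 8, 10))
  countries <- generate_countries(cfg, catalog = cat)
  s <- country_summary(countries)
  m <- function(col) tapply(s[[col]], s$income_group, mean)
  wf <- m("workforce_per_1000")
  expect_lt(wf[["low"]], wf[["upper_middle"]])
  pr <- m("unit_price_index")
  expect_lt(pr[["low"]], pr[["lower_middle"]])
  expect_lt(pr[["lower_middle"]], pr[["upper_middle"]])
  cv <- m("mean_baseline_coverage")
  expect_lt(cv[["low"]], cv[["upper_middle"]])
  # mortality: infant rate means ordered the other way
  inf_mx <- vapply(countries, function(co) {
    mr <- co$mortality_rate
    sum(mr$mx[mr$age_group == "0" & mr$cause_group != "stillbirth" &
                mr$sex == "female"])
  }, numeric(1))
  im <- tapply(inf_mx, s$income_group, mean)
  expect_gt(im[["low"]], im[["upper_middle"]])
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(n_countries = 0), "positive")
  gm <- tidyr::expand_grid(income_group = c("low"), maturity = c("hs1"))
  gm$prop <- 0.4
  expect_error(generator_config(group_mix = gm), "sum to 1")
})

test_that("profile invariants hold across seeds", {
  for (seed in c(4, 8, 15)) {
    cat <- generate_catalog(12, seed = seed, m_counts = c(6, 9, 11))
    countries <- generate_countries(
      generator_config(4, seed = seed, n_interventions = 12), catalog = cat)
    for (co in countries) {
      expect_identical(nrow(validate_country_profile(co)), 0L)
      expect_true(all(co$baseline_coverage$coverage >= 0 &
                        co$baseline_coverage$coverage <= 1))
      expect_true(all(co$mortality_rate$mx >= 0))
    }
  }
})

test_that("country tables round-trip to delimited text", {
  fix <- small_cohort(n = 3)
  dir <- withr::local_tempdir()
  write_country_tables(fix$countries, dir,
                       config = generator_config(3, seed = 11,
                                                 n_interventions = 40))
  expect_true(file.exists(file.path(dir, "countries.tsv")))
  back <- utils::read.delim(file.path(dir, "countries.tsv"))
  expect_identical(nrow(back), 3L)
  expect_true(file.exists(file.path(dir, "manifest.json")))
})
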