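# Impact model: residual combination, cause caps, life tables, HLY.

test_that("single-intervention averted deaths follow eff x delta-coverage", {
  # one cause, one intervention: 10,000 deaths, eff 0.7, coverage 0.3 -> 0.5
  ages <- phc_age_groups()
  mort <- tidyr::expand_grid(age_group = ages$age_group,
                             sex = c("female", "male"))
  mort$cause_group <- "ncd"
  mort$mx <- 0
  co <- make_test_country(pop_total = 1e6, mortality = mort)
  # put 10,000 deaths into one cell-set: rate so that total deaths = 10,000
  co$mortality_rate$mx <- 10000 / 1e6
  iv <- tibble::tibble(intervention_id = "A", effectiveness = 0.7,
                       cause_group = "ncd")
  out <- deaths_averted(co, iv, coverage_scaleup = 0.5,
                        coverage_flatline = 0.3, year = 2025)
  expect_equal(sum(out$deaths_averted), 10000 * 0.7 * 0.2)
  none <- deaths_averted(co, iv, 0.3, 0.3, 2025)
  expect_equal(sum(none$deaths_averted), 0)
  expect_warning(deaths_averted(co, iv, 0.2, 0.3, 2025), "decrease")
})

test_that("interventions on one cause combine on the residual", {
  co <- make_test_country(pop_total = 1e6)
  co$mortality_rate$mx <- 10000 / 1e6
  iv <- tibble::tibble(intervention_id = c("A", "B"),
                       effectiveness = c(1, 1),
                       cause_group = "other")
  out <- deaths_averted(co, iv, coverage_scaleup = c(0.6, 0.6),
                        coverage_flatline = c(0, 0), year = 2025)
  # 1 - (1 - 0.6)^2 = 0.84, not 1.2
  expect_equal(sum(out$deaths_averted), 10000 * 0.84)
  expect_lte(sum(out$deaths_averted), sum(out$deaths_baseline))
})

test_that("averted deaths are capped by cause deaths and monotone", {
  fix <- small_cohort(n = 3)
  co <- fix$countries[[1]]
  sub <- interventions_in_measure(fix$catalog, "m1")
  b <- co$baseline_coverage$coverage[
    match(sub$intervention_id, co$baseline_coverage$intervention_id)]
  out <- deaths_averted(co, sub, pmin(1, b + 0.3), b, 2030)
  expect_true(all(out$deaths_averted <= out$deaths_baseline + 1e-9))
  expect_true(all(out$deaths_averted >= 0))
  # monotone in coverage change
  out2 <- deaths_averted(co, sub, pmin(1, b + 0.15), b, 2030)
  expect_lte(sum(out2$deaths_averted), sum(out$deaths_averted))
  # monotone in effectiveness
  sub2 <- sub
  sub2$effectiveness <- sub$effectiveness / 2
  out3 <- deaths_averted(co, sub2, pmin(1, b + 0.3), b, 2030)
  expect_lte(sum(out3$deaths_averted), sum(out$deaths_averted))
})

test_that("external-cause adjustment subtracts cell-wise with a guard", {
  d <- tibble::tibble(age_group = c("0", "1-4"), deaths = c(500, 200))
  a <- tibble::tibble(age_group = "0", averted = 120)
  out <- external_cause_adjustment(d, a)
  expect_equal(out$deaths, c(380, 200))
  zero <- external_cause_adjustment(d, tibble::tibble(age_group = "0",
                                                      averted = 0))
  expect_equal(zero$deaths, d$deaths)
  expect_error(
    external_cause_adjustment(d, tibble::tibble(age_group = "0",
                                                averted = 501)),
    "exceed")
})

test_that("life table reproduces the abridged qx formula", {
  lt <- build_life_table(c(rep(0.01, 18), 0.1))
  # third interval: n = 5, ax = 2.5 -> qx = 0.05 / 1.025
  expect_equal(lt$qx[3], 0.05 / 1.025)
  expect_equal(lt$qx[19], 1)
  expect_equal(lt$lx[1], 1e5)
  expect_true(all(diff(lt$lx) <= 0))
  expect_true(all(diff(lt$Tx) <= 0))
  expect_true(all(lt$Lx >= 0))
})

test_that("constant hazard matches the exponential closed form", {
  n <- c(rep(1, 110), Inf)
  ax <- c(rep(0.5, 110), NA)
  for (h in c(0.001, 0.005, 0.02, 0.05, 0.1)) {
    lt <- build_life_table(rep(h, 111), n = n, ax = ax)
    expect_lt(abs(life_expectancy(lt) - 1 / h), 0.5)
  }
})

test_that("zero mortality in an interval passes survivors through", {
  mx <- c(rep(0.01, 18), 0.1)
  mx[4] <- 0
  lt <- build_life_table(mx)
  expect_equal(lt$qx[4], 0)
  expect_equal(lt$lx[5], lt$lx[4])
})

test_that("life-expectancy gain responds to averted deaths", {
  co <- make_test_country(pop_total = 1e6, mx_flat = 0.02)
  ages <- phc_age_groups()
  none <- tibble::tibble(age_group = ages$age_group, deaths_averted = 0)
  expect_equal(le_gain(co, none)$gain_vs_2015, 0)
  some <- none
  some$deaths_averted[3] <- 10
  expect_gt(le_gain(co, some)$gain_vs_2015, 0)
  # halving a constant 0.02 hazard roughly doubles e0 (50 -> 100)
  pop30 <- co$population[co$population$year == 2030, ]
  py <- tapply(pop30$pop, pop30$age_group, sum)[ages$age_group]
  half <- tibble::tibble(age_group = ages$age_group,
                         deaths_averted = unname(0.01 * py))
  lg <- le_gain(co, half)
  expect_lt(abs(lg$e0_2015 - 50), 1)
  expect_lt(abs(lg$e0_2030_scaleup - 100), 1)
  expect_lt(abs(lg$gain_vs_2015 - 50), 2)
  bad <- tibble::tibble(age_group = "200+", deaths_averted = 1)
  expect_error(le_gain(co, bad), "age structure")
})

test_that("healthy life-years difference weights states correctly", {
  w <- tibble::tibble(state = c("healthy", "sick"), weight = c(0, 0.2))
  fl <- tibble::tibble(state = c("healthy", "sick"), person_years = c(0, 1))
  su <- tibble::tibble(state = c("healthy", "sick"), person_years = c(1, 0))
  expect_equal(hly_gained(fl, su, w), 0.2)
  expect_equal(hly_gained(fl, fl, w), 0)
  wbad <- tibble::tibble(state = "sick", weight = 1.2)
  expect_error(hly_gained(fl, su, wbad), "\\[0, 1\\]")
})

test_that("averted deaths accrue horizon-bounded healthy life-years", {
  co <- make_test_country(pop_total = 1e6, mx_flat = 0.02)
  ages <- phc_age_groups()
  wts <- disability_weights()
  # independent oracle: remaining healthy life expectancy from the life
  # table, truncated at the horizon end
  lt <- build_life_table(rep(0.02, 19))
  rhle_40 <- lt$ex[ages$age_group == "40-44"] * 0.9
  one <- tibble::tibble(year = 2020, age_group = "40-44",
                        cause_group = "ncd", deaths_averted = 1)
  got <- hly_from_averted(co, one, wts)
  expect_equal(got$hly, min(rhle_40, 2030 - 2020 + 0.5))
  late <- tibble::tibble(year = 2030, age_group = "40-44",
                         cause_group = "ncd", deaths_averted = 1)
  expect_equal(hly_from_averted(co, late, wts)$hly, 0.5)
})

test_that("country impact bundle satisfies the under-5 identity", {
  fix <- small_cohort(n = 2)
  co <- fix$countries[[1]]
  im <- impact_country(co, fix$catalog, "m2")
  tot <- im$totals
  under5 <- sum(tot$deaths_averted[tot$cause_group %in%
                                     c("neonatal", "post_neonatal")])
  neo <- tot$deaths_averted[tot$cause_group == "neonatal"]
  post <- tot$deaths_averted[tot$cause_group == "post_neonatal"]
  expect_equal(neo + post, under5)
  expect_true(all(im$hly$hly >= 0))
  expect_gte(im$le$gain_vs_2015, 0)
})
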