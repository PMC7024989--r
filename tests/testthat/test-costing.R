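# Cost engine: op-level arithmetic contracts and engine-level invariants.

test_that("commodity cost is quantities times prices", {
  co <- make_test_country(pop_total = 1e6)
  iv <- list(intervention_id = "T1", target_pop_fraction = 1.0,
             in_need_fraction = 0.1, units_per_case = 2, commodity_price = 3)
  tr <- tibble::tibble(year = phc_years(), coverage = 0.6)
  expect_equal(commodity_cost(co, iv, tr, 2025), 360000)
  fl <- tibble::tibble(year = phc_years(), coverage = 0.4)
  expect_equal(commodity_cost(co, iv, tr, 2025, flatline_trajectory = fl),
               120000)
  expect_equal(commodity_cost(co, iv, tr, 2025, flatline_trajectory = tr), 0)
  iv$commodity_price <- NA_real_
  expect_error(commodity_cost(co, iv, tr, 2025), "T1")
  iv$commodity_price <- 3
  expect_error(commodity_cost(co, iv, tr, 2015), "2020-2030")
})

test_that("FTE requirement divides service minutes by worker capacity", {
  expect_equal(fte_requirement(100000 * 19.8, 99000), 20)
  expect_equal(fte_requirement(0, 99000), 0)
  expect_equal(fte_requirement(2 * 100000 * 19.8, 99000),
               2 * fte_requirement(100000 * 19.8, 99000))
  expect_error(fte_requirement(100, 0), "positive")
})

test_that("workforce cost applies the PHC minute share to the density target", {
  wf <- phc_workforce_cost(20, 50, density_target = 6.0, population = 1e6,
                           salary = 5000)
  expect_equal(wf$phc_share, 0.4)
  expect_equal(wf$workforce, 2400)
  expect_equal(wf$cost, 12e6)
  expect_equal(phc_workforce_cost(30, 30, 6, 1e6, 5000)$phc_share, 1)
  expect_equal(phc_workforce_cost(0, 0, 6, 1e6, 5000)$phc_share, 0)
  # current workforce above requirement floors the increment at zero
  expect_equal(phc_workforce_cost(20, 50, 6, 1e6, 5000,
                                  current_workers = 3000)$incremental_workers,
               0)
  expect_error(phc_workforce_cost(60, 50, 6, 1e6, 5000), "fte_phc")
})

test_that("facility shares follow the published hospital allocation", {
  m1 <- measure_spec("m1"); m2 <- measure_spec("m2")
  expect_equal(unname(infrastructure_cost(c(district_hospital = 100), m1)), 33)
  expect_equal(unname(infrastructure_cost(c(district_hospital = 100), m2)), 81)
  expect_equal(unname(infrastructure_cost(c(provincial_hospital = 100), m1)), 3)
  expect_equal(unname(infrastructure_cost(c(provincial_hospital = 100), m2)), 27)
  expect_equal(unname(infrastructure_cost(c(health_centre = 100), m1)), 100)
  expect_equal(unname(infrastructure_cost(c(health_centre = 100), m2)), 100)
  expect_error(infrastructure_cost(c(clinic = 1), m1), "named by level")
})

test_that("shared components scale per measure scope", {
  m1 <- measure_spec("m1"); m2 <- measure_spec("m2"); m3 <- measure_spec("m3")
  expect_equal(shared_system_cost("governance", 50, m1), 40)
  expect_equal(shared_system_cost("governance", 50, m2), 50)
  expect_equal(shared_system_cost("financing", 50, m1), 40)
  expect_equal(shared_system_cost("supply_chain", 200, m1,
                                  commodity_ratio = 0.35), 70)
  expect_equal(shared_system_cost("cold_chain", 10, m1), 10)
  expect_equal(shared_system_cost("cold_chain", 10, m3), 10)
  expect_equal(shared_system_cost("emergency_relief", 7, m1), 7)
  expect_equal(shared_system_cost("cash_transfers", 100, m1), 0)
  expect_gt(shared_system_cost("cash_transfers", 100, m3),
            shared_system_cost("cash_transfers", 100, m2))
  expect_equal(shared_system_cost("cross_sectoral", 100, m2), 0)
  expect_equal(shared_system_cost("cross_sectoral", 100, m3), 100)
  expect_error(shared_system_cost("supply_chain", 200, m1), "commodity_ratio")
  expect_error(shared_system_cost("canteen", 1, m1), "unknown")
})

test_that("capital redistribution conserves totals and spreads uniformly", {
  led <- tibble::tibble(
    country_id = "X", year = c(2016:2019, 2022),
    measure_id = "m1", component = "infrastructure",
    cost_type = c(rep("capital", 4), "recurrent"),
    amount = c(11, 11, 11, 11, 5))
  out <- redistribute_capital(led)
  cap <- out[out$cost_type == "capital", ]
  expect_setequal(cap$year, 2020:2030)
  expect_equal(cap$amount, rep(4, 11))
  expect_equal(sum(cap$amount), 44)
  expect_equal(out$amount[out$cost_type == "recurrent"], 5)
  # no capital in source years -> unchanged
  rec_only <- led[led$cost_type == "recurrent", ]
  expect_equal(redistribute_capital(rec_only), rec_only)
  expect_error(redistribute_capital(led, 2016:2021, 2020:2030), "overlap")
})

test_that("aggregation sums, averages and divides per capita", {
  led <- tibble::tibble(
    country_id = c("A", "B", "C"), year = 2025, measure_id = "m1",
    component = "workforce", cost_type = "recurrent",
    amount = c(30, 77, 72) * 1e9)
  tot <- aggregate_costs(led, measure_id)
  expect_equal(tot$amount, 179e9)
  one <- aggregate_costs(led[2, ], country_id)
  expect_equal(one$amount, 77e9)
  pc <- aggregate_costs(tibble::tibble(amount = 65e6, year = 1,
                                       cost_type = "recurrent"),
                        population = 1e6)
  expect_equal(pc$amount_per_capita, 65)
})

test_that("engine satisfies nesting monotonicity, conservation and homogeneity", {
  fix <- small_cohort(n = 4)
  for (co in fix$countries) {
    leds <- lapply(c("m1", "m2", "m3"), function(m)
      cost_country(co, fix$catalog, m))
    tot <- vapply(leds, function(l) sum(l$amount), numeric(1))
    expect_true(all(diff(tot) >= -1e-9 * tot[1]))
    by_year <- lapply(leds, function(l) tapply(l$amount, l$year, sum))
    expect_true(all(by_year[[1]] <= by_year[[2]] + 1e-6 * abs(by_year[[2]])))
    expect_true(all(by_year[[2]] <= by_year[[3]] + 1e-6 * abs(by_year[[3]])))
    # conservation: component sums equal grand total
    l1 <- leds[[1]]
    expect_equal(sum(aggregate_costs(l1, component)$amount), sum(l1$amount))
    expect_true(all(l1$amount >= 0))
    expect_true(all(l1$year %in% 2020:2030))
  }
  # homogeneity: doubling all prices doubles all costs
  co <- fix$countries[[1]]
  co2 <- co
  co2$unit_price_index <- 2 * co$unit_price_index
  a <- cost_country(co, fix$catalog, "m1")
  b <- cost_country(co2, fix$catalog, "m1")
  expect_equal(b$amount, 2 * a$amount)
})

test_that("zero scale-up produces zero incremental cost", {
  co <- make_test_country(maturity = "hs3",
                          baselines = c(T1 = 0.95, T2 = 0.95))
  led <- cost_country(co, tiny_catalog(), "m2")
  expect_equal(sum(abs(led$amount)), 0)
})
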