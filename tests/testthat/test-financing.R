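# Financing scenarios and funding gaps.

test_that("flat history extrapolates flat under business as usual", {
  co <- make_test_country(che_hist = rep(5, 5))
  pr <- project_che(co, "bau")
  expect_equal(pr$che_pct_gdp, rep(5, 11))
  expect_equal(pr$year, 2020:2030)
})

test_that("progress scenarios ramp to +1/+2 points of GDP by 2030", {
  co <- make_test_country(che_hist = rep(5, 5))
  p1 <- project_che(co, "progress1")
  expect_equal(p1$che_pct_gdp[p1$year == 2030], 6.0)
  expect_equal(p1$che_pct_gdp[p1$year == 2025], 5 + 6 / 11)
  p2 <- project_che(co, "ambitious2")
  expect_equal(p2$che_pct_gdp[p2$year == 2030], 7.0)
  bau <- project_che(co, "bau")
  expect_true(all(p2$che_pct_gdp >= p1$che_pct_gdp))
  expect_true(all(p1$che_pct_gdp >= bau$che_pct_gdp))
})

test_that("scenario funds are floors over a fast historical trend", {
  # trend of +0.3 pp/year beats the +1pp/11y path; funds must not shrink
  co <- make_test_country(che_hist = 5 + 0.3 * (0:4))
  bau <- project_che(co, "bau")
  p1 <- project_che(co, "progress1")
  expect_true(all(p1$che_pct_gdp >= bau$che_pct_gdp - 1e-9))
})

test_that("bau requires history and clamps extrapolation", {
  co <- make_test_country()
  co$che_pct_gdp <- co$che_pct_gdp[1:2, ]
  expect_error(project_che(co, "bau"), "3 historical")
  steep <- make_test_country(che_hist = c(20, 21, 22, 23, 24))
  pr <- project_che(steep, "bau")
  expect_true(all(pr$che_pct_gdp <= 25))
  falling <- make_test_country(che_hist = c(3.0, 2.5, 2.0, 1.5, 1.0))
  expect_true(all(project_che(falling, "bau")$che_pct_gdp >= 1))
})

test_that("funding gap is the positive excess of cost over allocated funds", {
  co <- make_test_country(pop_total = 1e6, gdp_pc = 1000,
                          che_hist = rep(5, 5), growth = 0)
  p1 <- project_che(co, "progress1")
  funds_2030 <- p1$incremental_funds[p1$year == 2030] # 1% of GDP x pop = 10M
  expect_equal(funds_2030, 10e6)
  expect_equal(funding_gap(p1, 5e6, 2030), 0)
  expect_equal(funding_gap(p1, 5e6, 2030, phc_allocation = 1 / 3),
               5e6 - 10e6 / 3)
  expect_equal(funding_gap(p1, 0, 2030), 0)
  expect_error(funding_gap(p1, 1, 2030, phc_allocation = 0), "\\(0, 1\\]")
  # gap is non-increasing in the allocation share
  gaps <- vapply(c(0.2, 0.5, 0.8, 1),
                 function(a) funding_gap(p1, 8e6, 2030, a), numeric(1))
  expect_true(all(diff(gaps) <= 0))
})

test_that("gap-country counts invert the gap formula on an engineered cohort", {
  # constant GDP and flat expenditure share: bau incremental funds are zero,
  # so exactly the countries with positive cost show a gap
  cohort <- lapply(1:20, function(i)
    make_test_country(id = sprintf("G%02d", i), growth = 0,
                      che_hist = rep(5, 5)))
  projs <- lapply(cohort, project_che, scenario = "bau")
  costs <- stats::setNames(rep(0, 20), vapply(cohort, `[[`, "",
                                              "country_id"))
  costs[1:5] <- 1e6
  expect_identical(count_gap_countries(projs, costs, 2030), 5L)
  expect_identical(count_gap_countries(projs, 0 * costs, 2030), 0L)
})

test_that("gap counts are anti-monotone across scenarios", {
  fix <- small_cohort(n = 6)
  costs <- vapply(fix$countries, function(co)
    sum(cost_country(co, fix$catalog, "m1")$amount) / 11, numeric(1))
  names(costs) <- vapply(fix$countries, `[[`, "", "country_id")
  counts <- vapply(c("bau", "progress1", "ambitious2"), function(sc) {
    projs <- lapply(fix$countries, project_che, scenario = sc)
    count_gap_countries(projs, costs, 2030)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})
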