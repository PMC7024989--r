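# Catalog structure: printed measure sizes, nesting, validation.

test_that("default catalog reproduces the published measure sizes", {
  cat <- generate_catalog()
  expect_identical(nrow(cat), 188L)
  expect_identical(sum(cat$m1), 143L)
  expect_identical(sum(cat$m2), 152L)
  expect_identical(sum(cat$m3), 160L)
  expect_true(all(cat$m1 <= cat$m2))
  expect_true(all(cat$m2 <= cat$m3))
  expect_identical(nrow(validate_catalog(cat)), 0L)
})

test_that("named example interventions sit in their measure blocks", {
  cat <- generate_catalog()
  row <- function(nm) cat[cat$name == nm, ]
  expect_true(row("Family planning")$m1)
  expect_true(row("Childhood vaccination programme")$m1)
  nd <- row("Normal delivery care")
  expect_false(nd$m1); expect_true(nd$m2)
  ws <- row("Water and sanitation")
  expect_false(ws$m2); expect_true(ws$m3)
  expect_identical(ws$platform, "cross_sectoral")
})

test_that("small catalogs honour requested nested sizes", {
  cat <- generate_catalog(10, seed = 5, m_counts = c(6, 8, 10))
  expect_identical(c(sum(cat$m1), sum(cat$m2), sum(cat$m3)), c(6L, 8L, 10L))
  expect_true(all(cat$m1 <= cat$m2) && all(cat$m2 <= cat$m3))
  expect_error(generate_catalog(10, m_counts = c(8, 6, 10)), "non-decreasing")
  expect_error(generate_catalog(5, m_counts = c(2, 3, 9)), "non-decreasing|size")
})

test_that("interventions_in_measure returns nested subsets", {
  cat <- generate_catalog(30, seed = 2, m_counts = c(15, 20, 25))
  s1 <- interventions_in_measure(cat, "m1")
  s2 <- interventions_in_measure(cat, measure_spec("m2"))
  s3 <- interventions_in_measure(cat, "m3")
  expect_identical(nrow(s1), 15L)
  expect_true(all(s1$intervention_id %in% s2$intervention_id))
  expect_true(all(s2$intervention_id %in% s3$intervention_id))
  empty <- cat[0, ]
  expect_identical(nrow(interventions_in_measure(empty, "m1")), 0L)
  expect_error(interventions_in_measure(cat, "m4"), "unknown measure")
})

test_that("validate_catalog reports nesting and range violations", {
  cat <- generate_catalog(10, seed = 5, m_counts = c(6, 8, 10))
  broken <- cat
  broken$m3[1] <- FALSE # still m1 -> nesting break
  v <- validate_catalog(broken)
  expect_true(any(v$field == "nesting"))
  broken2 <- cat
  broken2$effectiveness[2] <- 1.4
  v2 <- validate_catalog(broken2)
  expect_identical(v2$field, "effectiveness")
  expect_identical(v2$intervention_id, cat$intervention_id[2])
  expect_error(interventions_in_measure(broken, "m1"), "nesting")
})

test_that("measure specs carry the published allocation shares", {
  m1 <- measure_spec("m1"); m2 <- measure_spec("m2"); m3 <- measure_spec("m3")
  expect_equal(m1$district_hospital_share, 0.33)
  expect_equal(m1$provincial_hospital_share, 0.03)
  expect_equal(m2$district_hospital_share, 0.81)
  expect_equal(m2$provincial_hospital_share, 0.27)
  expect_equal(m1$governance_share, 0.80)
  expect_equal(m2$governance_share, 1.00)
  expect_equal(m1$health_centre_share, 1.0)
  expect_equal(m3$health_centre_share, 1.0)
  expect_identical(m3$his_scope, "full_sector_plus_census")
  expect_identical(m3$cash_transfer_scope, "general")
  expect_true(m3$includes_cross_sectoral)
  expect_false(m2$includes_cross_sectoral)
})
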