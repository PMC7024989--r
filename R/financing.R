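# Financing scenarios: health expenditure as a share of GDP projected under
# business-as-usual (historical trend), +1 and +2 percentage-point-of-GDP
# paths, with PHC funding gaps counted against incremental costs.

phc_scenarios <- function() c("bau", "progress1", "ambitious2")

#' Project current health expenditure for one country
#'
#' Business-as-usual extrapolates the country's historical linear trend of
#' health expenditure as a share of GDP (ordinary least squares, clamped to
#' 1-25% to prevent pathological extrapolation). The progress scenarios
#' follow a linear path from the 2019 level to +1 or +2 percentage points of
#' GDP by 2030, applied as a floor over the business-as-usual trend so that
#' countries already on a faster trajectory are not assumed to slow down.
#'
#' @param country A `country_profile` (with at least 3 historical
#'   expenditure points for business-as-usual).
#' @param scenario One of `"bau"`, `"progress1"`, `"ambitious2"`.
#' @return A tibble (`country_id`, `scenario`, `year` 2020-2030, `che_pct_gdp`,
#'   `che_per_capita`, `incremental_funds_per_capita`, `incremental_funds`),
#'   incremental amounts measured against the 2019 expenditure level.
#' @export
project_che <- function(country, scenario = c("bau", "progress1",
                                              "ambitious2")) {
  scenario <- match.arg(scenario)
  hist <- country$che_pct_gdp
  if (nrow(hist) < 3) {
    stop("need at least 3 historical expenditure points", call. = FALSE)
  }
  years <- phc_horizon()
  fit <- stats::lm(che_pct ~ year, data = hist)
  bau <- stats::predict(fit, newdata = data.frame(year = years))
  bau <- pmin(25, pmax(1, unname(bau)))
  level_2019 <- hist$che_pct[hist$year == max(hist$year)]

  pct <- switch(scenario,
    bau = bau,
    progress1 = pmax(bau, level_2019 + 1 * (years - 2019) / 11),
    ambitious2 = pmax(bau, level_2019 + 2 * (years - 2019) / 11))

  gdp <- country$gdp_per_capita
  gdp_pc <- gdp$gdp_pc[match(years, gdp$year)]
  che_pc <- pct / 100 * gdp_pc
  che_pc_2019 <- level_2019 / 100 * gdp$gdp_pc[gdp$year == 2019]
  popy <- unname(population_total(country, years))
  inc_pc <- pmax(0, che_pc - che_pc_2019)
  tibble::tibble(country_id = country$country_id, scenario = scenario,
                 year = years, che_pct_gdp = pct, che_per_capita = che_pc,
                 incremental_funds_per_capita = inc_pc,
                 incremental_funds = inc_pc * popy)
}

#' PHC funding gap in one year
#'
#' `gap = max(0, incremental PHC cost - phc_allocation x incremental funds)`:
#' the positive excess of the year's incremental PHC cost over the share of
#' incremental health funds countable against PHC.
#'
#' @param projection A projection from [project_che()].
#' @param phc_cost Incremental PHC cost for the year (US$), or a ledger
#'   tibble to be summed for the year.
#' @param year Calendar year.
#' @param phc_allocation Fraction of incremental funds allocated to PHC, in
#'   `(0, 1]`. Default 1 (the published allocation rule is not public; this
#'   is deliberately generous and config-exposed).
#' @return Gap amount in US$ (non-negative).
#' @export
funding_gap <- function(projection, phc_cost, year, phc_allocation = 1) {
  if (phc_allocation <= 0 || phc_allocation > 1) {
    stop("phc_allocation must lie in (0, 1]", call. = FALSE)
  }
  if (is.data.frame(phc_cost)) {
    phc_cost <- sum(phc_cost$amount[phc_cost$year == year])
  }
  funds <- projection$incremental_funds[projection$year == year]
  if (!length(funds)) stop("projection does not cover year ", year,
                           call. = FALSE)
  max(0, phc_cost - phc_allocation * funds)
}

#' Count countries with a funding gap
#'
#' @param projections List of [project_che()] tibbles (one scenario).
#' @param costs Named numeric vector of incremental PHC costs by country id
#'   for the year, or a combined ledger tibble with `country_id`.
#' @param year Calendar year.
#' @param phc_allocation As in [funding_gap()].
#' @return Integer count of countries whose gap is strictly positive. Counts
#'   are non-increasing from business-as-usual to the +1 and +2 point
#'   scenarios.
#' @export
count_gap_countries <- function(projections, costs, year, phc_allocation = 1) {
  if (is.data.frame(costs)) {
    cs <- costs[costs$year == year, ] |>
      dplyr::group_by(.data$country_id) |>
      dplyr::summarise(amount = sum(.data$amount), .groups = "drop")
    costs <- stats::setNames(cs$amount, cs$country_id)
  }
  gaps <- vapply(projections, function(pr) {
    cid <- pr$country_id[1]
    funding_gap(pr, unname(costs[cid]) %|NA|% 0, year, phc_allocation)
  }, numeric(1))
  sum(gaps > 0)
}

`%|NA|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a
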