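# Impact model: coverage scale-up -> deaths averted -> life-expectancy and
# healthy-life-year gains versus the flatline counterfactual.
#
# The disease-specific projection engines of the parent tool are not
# reproducible; this module uses a declared coverage-effectiveness stand-in:
# each intervention averts `effectiveness x (coverage gain)` of the deaths of
# its cause group, and interventions addressing the same cause combine on the
# residual (never exceeding the cause's baseline deaths). Magnitudes
# therefore differ from the published totals by construction; structure,
# signs and accounting identities are the reliable outputs.

#' Deaths averted in one country-year
#'
#' For each cause group the combined averted fraction is
#' `1 - prod(1 - effectiveness_i * max(0, cov_scaleup_i - cov_flatline_i))`
#' over the interventions addressing the cause; deaths averted are the cause
#' deaths times that fraction, cell-wise by age group and sex, and can never
#' exceed the cause deaths. Coverage decreases contribute zero (with a
#' warning).
#'
#' @param country A `country_profile`.
#' @param interventions Catalog rows to credit (e.g. a measure subset).
#' @param coverage_scaleup,coverage_flatline Per-intervention coverage values
#'   for the year, aligned with `interventions` (e.g. one year's column of
#'   the scale-up and flatline trajectories).
#' @param year Calendar year (sets the exposed population).
#' @return Tibble `age_group`, `sex`, `cause_group`, `deaths_baseline`,
#'   `deaths_averted` for the year.
#' @export
deaths_averted <- function(country, interventions, coverage_scaleup,
                           coverage_flatline, year) {
  dcov <- coverage_scaleup - coverage_flatline
  if (any(dcov < -1e-12)) {
    warning("coverage decrease treated as zero contribution")
  }
  dcov <- pmax(dcov, 0)
  eff <- interventions$effectiveness
  frac <- tapply(1 - eff * dcov, interventions$cause_group, prod)
  frac <- 1 - frac

  pop <- country$population
  popy <- pop[pop$year == year, c("age_group", "sex", "pop")]
  mr <- country$mortality_rate
  out <- dplyr::inner_join(mr, popy, by = c("age_group", "sex"))
  out$deaths_baseline <- out$mx * out$pop
  f <- frac[out$cause_group]
  f[is.na(f)] <- 0
  out$deaths_averted <- out$deaths_baseline * f
  out$year <- as.integer(year)
  out[, c("year", "age_group", "sex", "cause_group",
          "deaths_baseline", "deaths_averted")]
}

#' Subtract externally modelled averted deaths
#'
#' Deaths averted for causes modelled outside the main engine (tuberculosis,
#' neglected tropical diseases, cervical cancer screening) are subtracted
#' cell-wise from the projected death counts.
#'
#' @param deaths Tibble with a `deaths` column (any cell structure).
#' @param averted Tibble with the same cell columns and an `averted` column;
#'   every cell's averted count must not exceed its deaths.
#' @return `deaths` with the `deaths` column reduced cell-wise.
#' @export
external_cause_adjustment <- function(deaths, averted) {
  keys <- setdiff(intersect(names(deaths), names(averted)),
                  c("deaths", "averted"))
  if (!length(keys)) stop("no common cell columns", call. = FALSE)
  out <- dplyr::left_join(deaths, averted[, c(keys, "averted")], by = keys)
  out$averted[is.na(out$averted)] <- 0
  if (any(out$averted > out$deaths + 1e-9)) {
    stop("averted deaths exceed projected deaths in at least one cell",
         call. = FALSE)
  }
  out$deaths <- out$deaths - out$averted
  out$averted <- NULL
  out
}

#' Life-expectancy gain from averted deaths
#'
#' Rebuilds the 2030 period life table with mortality net of averted deaths:
#' averted deaths by age group (both sexes combined) convert to rate
#' reductions through the mid-year person-years of the age group. Returns
#' the gain in life expectancy at birth against the 2015 baseline table and
#' against the 2030 flatline table.
#'
#' @param country A `country_profile`.
#' @param averted_by_age Tibble `age_group`, `deaths_averted` for 2030 (e.g.
#'   from [deaths_averted()], stillbirths excluded).
#' @param flatline_mx Optional baseline mx by age group (defaults to the
#'   profile's all-cause rates, i.e. a flatline mortality projection).
#' @return List with `e0_2015`, `e0_2030_flatline`, `e0_2030_scaleup`,
#'   `gain_vs_2015`, `gain_vs_flatline`.
#' @export
le_gain <- function(country, averted_by_age, flatline_mx = NULL) {
  ages <- phc_age_groups()
  mr <- country$mortality_rate
  mr <- mr[mr$cause_group != "stillbirth", ]
  pop30 <- country$population[country$population$year == 2030, ]
  py <- tapply(pop30$pop, pop30$age_group, sum)[ages$age_group]

  if (is.null(flatline_mx)) {
    d <- dplyr::inner_join(mr, pop30[, c("age_group", "sex", "pop")],
                           by = c("age_group", "sex"))
    deaths <- tapply(d$mx * d$pop, d$age_group, sum)[ages$age_group]
    flatline_mx <- unname(deaths / py)
  }
  if (length(flatline_mx) != nrow(ages)) {
    stop("age structure mismatch between mx and the abridged layout",
         call. = FALSE)
  }
  av <- stats::setNames(rep(0, nrow(ages)), ages$age_group)
  got <- tapply(averted_by_age$deaths_averted, averted_by_age$age_group, sum)
  if (!all(names(got) %in% ages$age_group)) {
    stop("age structure mismatch in averted deaths", call. = FALSE)
  }
  av[names(got)] <- got
  mx_scaleup <- pmax(0, flatline_mx - unname(av / py))

  lt15 <- build_life_table(flatline_mx, n = ages$n)
  lt30 <- build_life_table(mx_scaleup, n = ages$n)
  list(e0_2015 = life_expectancy(lt15),
       e0_2030_flatline = life_expectancy(lt15),
       e0_2030_scaleup = life_expectancy(lt30),
       gain_vs_2015 = life_expectancy(lt30) - life_expectancy(lt15),
       gain_vs_flatline = life_expectancy(lt30) - life_expectancy(lt15))
}

#' Healthy life-years gained between scenarios
#'
#' Compares person-years lived by health state between the flatline and
#' scale-up populations, weighting each state by one minus its disability
#' weight: `HLY = sum((py_scaleup - py_flatline) * (1 - weight))`.
#' Identical scenarios yield zero.
#'
#' @param flatline_pop_health,scaleup_pop_health Tibbles `state`,
#'   `person_years` (extra grouping columns allowed and preserved).
#' @param disability_weights Tibble `state`, `weight` with weights in
#'   `[0, 1]` (healthy = 0).
#' @return Total healthy life-years gained (scalar).
#' @export
hly_gained <- function(flatline_pop_health, scaleup_pop_health,
                       disability_weights) {
  if (any(disability_weights$weight < 0 | disability_weights$weight > 1)) {
    stop("disability weights must lie in [0, 1]", call. = FALSE)
  }
  hl <- function(df) {
    m <- dplyr::left_join(df, disability_weights, by = "state")
    if (anyNA(m$weight)) stop("missing disability weight for some states",
                              call. = FALSE)
    sum(m$person_years * (1 - m$weight))
  }
  hl(scaleup_pop_health) - hl(flatline_pop_health)
}

#' Default disability weights by cause group
#'
#' Read from the packaged reference table (editable copy under
#' `inst/extdata/disability_weights.tsv`); weights are representative
#' burden-of-disease style values for the modelled state of each cause
#' group.
#'
#' @return Tibble `cause_group`, `disease_area`, `weight`.
#' @export
disability_weights <- function() {
  path <- system.file("extdata", "disability_weights.tsv",
                      package = "phcguideposts")
  tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Healthy life-years from averted deaths and stillbirths
#'
#' Each death averted in year `t` accrues the remaining healthy life
#' expectancy at its age, truncated at the end of the investment horizon
#' (2030); stillbirths averted accrue from birth. Healthy life expectancy is
#' the life-table expectation scaled by one minus the population-average
#' disability weight.
#'
#' @param country A `country_profile`.
#' @param averted Tibble `year`, `age_group`, `cause_group`,
#'   `deaths_averted`.
#' @param weights Disability weight table from [disability_weights()].
#' @param mean_weight Average disability weight of survivors (discounts the
#'   healthy expectancy), default 0.1.
#' @return Tibble `disease_area`, `hly` (healthy life-years, horizon-bounded).
#' @export
hly_from_averted <- function(country, averted, weights = disability_weights(),
                             mean_weight = 0.1) {
  ages <- phc_age_groups()
  mr <- country$mortality_rate
  mr <- mr[mr$cause_group != "stillbirth", ]
  pop15 <- country$population[country$population$year == 2015, ]
  py <- tapply(pop15$pop, pop15$age_group, sum)[ages$age_group]
  d <- dplyr::inner_join(mr, pop15[, c("age_group", "sex", "pop")],
                         by = c("age_group", "sex"))
  deaths <- tapply(d$mx * d$pop, d$age_group, sum)[ages$age_group]
  lt <- build_life_table(unname(deaths / py), n = ages$n)
  rhle <- stats::setNames(lt$ex * (1 - mean_weight), ages$age_group)

  out <- averted
  out$rhle <- rhle[out$age_group]
  out$rhle[out$cause_group == "stillbirth"] <- rhle[["0"]]
  out$years_left <- pmax(0, 2030 - out$year + 0.5)
  out$hly <- out$deaths_averted * pmin(out$rhle, out$years_left)
  out <- dplyr::left_join(out, weights[, c("cause_group", "disease_area")],
                          by = "cause_group")
  out$disease_area[is.na(out$disease_area)] <- "other"
  dplyr::summarise(dplyr::group_by(out, .data$disease_area),
                   hly = sum(.data$hly), .groups = "drop")
}

#' Full impact projection for one country and measure
#'
#' Runs the coverage-effectiveness model over the investment horizon:
#' deaths averted by year, age, sex and cause; life-expectancy gain at 2030
#' (tuberculosis, NTD and cervical-cancer deaths are removed from the 2030
#' death counts through the external-cause adjustment path, mirroring how
#' those impacts are computed outside the main engine); healthy life-years
#' by disease area, including a morbidity term crediting persons effectively
#' treated in the year with their state's disability weight.
#'
#' @inheritParams cost_country
#' @return List with `averted` (tidy by year/age/sex/cause), `totals` (by
#'   cause group, 2020-2030 sum), `le` (life-expectancy gain list), and
#'   `hly` (by disease area).
#' @export
impact_country <- function(country, catalog, measure,
                           params = costing_params()) {
  if (!inherits(measure, "measure_spec")) measure <- measure_spec(measure)
  sub <- interventions_in_measure(catalog, measure)
  base <- country$baseline_coverage$coverage[
    match(sub$intervention_id, country$baseline_coverage$intervention_id)]
  S <- coverage_matrix(base, country$maturity, scaleup = TRUE)
  F <- coverage_matrix(base, country$maturity, scaleup = FALSE)
  horizon <- phc_horizon()

  averted <- purrr::map_dfr(horizon, function(y) {
    deaths_averted(country, sub, S[, as.character(y)], F[, as.character(y)], y)
  })
  totals <- averted |>
    dplyr::group_by(.data$cause_group) |>
    dplyr::summarise(deaths_averted = sum(.data$deaths_averted),
                     .groups = "drop")

  # life table path: deaths in 2030 net of averted; TB, NTD and cervical
  # cancer go through the external-adjustment route
  av30 <- averted[averted$year == 2030 &
                    averted$cause_group != "stillbirth", ]
  external_causes <- c("tb", "ntd", "cancer")
  internal <- av30[!av30$cause_group %in% external_causes, ]
  external <- av30[av30$cause_group %in% external_causes, ]
  int_by_age <- internal |>
    dplyr::group_by(.data$age_group) |>
    dplyr::summarise(deaths = sum(.data$deaths_baseline) -
                       sum(.data$deaths_averted), .groups = "drop")
  ext_by_age <- external |>
    dplyr::group_by(.data$age_group) |>
    dplyr::summarise(deaths = sum(.data$deaths_baseline),
                     averted = sum(.data$deaths_averted), .groups = "drop")
  adj <- external_cause_adjustment(
    dplyr::bind_rows(int_by_age,
                     ext_by_age[, c("age_group", "deaths")]) |>
      dplyr::group_by(.data$age_group) |>
      dplyr::summarise(deaths = sum(.data$deaths), .groups = "drop"),
    ext_by_age[, c("age_group", "averted")])
  # total averted by age = baseline deaths - adjusted deaths
  base_by_age <- av30 |>
    dplyr::group_by(.data$age_group) |>
    dplyr::summarise(deaths = sum(.data$deaths_baseline), .groups = "drop")
  av_by_age <- dplyr::left_join(base_by_age, adj, by = "age_group",
                                suffix = c("_base", "_adj"))
  av_by_age$deaths_averted <- av_by_age$deaths_base - av_by_age$deaths_adj
  le <- le_gain(country, av_by_age[, c("age_group", "deaths_averted")])

  wts <- disability_weights()
  hly_mort <- hly_from_averted(country, averted, wts)
  # morbidity term: persons effectively treated this year leave their
  # disease state for the year
  popy <- population_total(country)
  tpf <- sub$target_pop_fraction * sub$in_need_fraction
  dR <- pmax(S - F, 0)[, as.character(horizon), drop = FALSE] * tpf *
    rep(unname(popy[as.character(horizon)]), each = nrow(sub))
  w <- wts$weight[match(sub$cause_group, wts$cause_group)]
  area <- wts$disease_area[match(sub$cause_group, wts$cause_group)]
  hly_morb <- tibble::tibble(
    disease_area = area,
    hly = rowSums(dR) * sub$effectiveness * w) |>
    dplyr::group_by(.data$disease_area) |>
    dplyr::summarise(hly = sum(.data$hly), .groups = "drop")
  hly <- dplyr::bind_rows(hly_mort, hly_morb) |>
    dplyr::group_by(.data$disease_area) |>
    dplyr::summarise(hly = sum(.data$hly), .groups = "drop")

  list(country_id = country$country_id, measure_id = measure$measure_id,
       averted = averted, totals = totals, le = le, hly = hly)
}
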