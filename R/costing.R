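# Ingredients-based cost engine: every investment is a quantity-by-year
# multiplied by a price. Intervention commodities are costed directly from
# persons reached; the workforce requirement is built bottom-up from service
# minutes; facility infrastructure carries measure-specific hospital shares;
# shared health-system components are scoped per measure; capital modelled
# for 2016-19 is redistributed into the 2020-30 investment window.

phc_components <- function() {
  c("commodities", "workforce", "infrastructure", "equipment", "supply_chain",
    "cold_chain", "his", "governance", "financing", "emergency",
    "cash_transfers", "cross_sectoral", "programme_support")
}

#' Reference price and quantity parameters for the cost engine
#'
#' All monetary parameters are reference US$2014 values scaled by each
#' country's `unit_price_index`. Facility and shared-system envelopes are
#' expressed per capita per unit of mean coverage gain, so a country with no
#' scale-up incurs no incremental system cost.
#'
#' @param minutes_per_fte_year Available service minutes per full-time
#'   equivalent worker-year (default 99 000, about 225 working days of
#'   clinical contact time).
#' @param salary_per_fte Reference annual salary (plus in-service training)
#'   per FTE, US$2014.
#' @param density_target Health workers per 1000 population targeted by the
#'   parent full-package projection; the PHC requirement is a share of it.
#' @param infra_capital_pc,equipment_capital_pc Named per-capita capital
#'   reference costs by facility level, spread over the 2016-2030 build-out.
#' @param maintenance_frac Recurrent maintenance as a fraction of the annual
#'   capital flow.
#' @param shared_pc Named per-capita envelopes for shared system components.
#' @param his_scope_factor,emergency_scope_factor,cash_scope_factor Scope
#'   multipliers looked up from the measure specification.
#' @param programme_support_rate Markup on direct intervention costs.
#' @param capital_build_years Years over which facility capital is modelled
#'   before redistribution into the investment window.
#' @return A `costing_params` list.
#' @export
costing_params <- function(
    minutes_per_fte_year = 99000,
    salary_per_fte = 10000,
    density_target = 8.9,
    infra_capital_pc = c(health_centre = 250, district_hospital = 220,
                         provincial_hospital = 180),
    equipment_capital_pc = c(health_centre = 80, district_hospital = 70,
                             provincial_hospital = 60),
    maintenance_frac = 0.25,
    shared_pc = c(supply_chain = 6, cold_chain = 0.8, his = 6,
                  governance = 8, financing = 5, emergency = 5,
                  cash_transfers = 8, cross_sectoral = 35),
    his_scope_factor = c(facility_only = 0.6, full_sector = 1,
                         full_sector_plus_census = 1.3),
    emergency_scope_factor = c(lab_share_only = 0.33, full_preparedness = 1),
    cash_scope_factor = c(none = 0, birth_only = 0.25, general = 1),
    programme_support_rate = 0.10,
    capital_build_years = 2016:2030) {
  stopifnot(minutes_per_fte_year > 0, salary_per_fte >= 0, density_target > 0)
  structure(list(
    minutes_per_fte_year = minutes_per_fte_year,
    salary_per_fte = salary_per_fte,
    density_target = density_target,
    infra_capital_pc = infra_capital_pc,
    equipment_capital_pc = equipment_capital_pc,
    maintenance_frac = maintenance_frac,
    shared_pc = shared_pc,
    his_scope_factor = his_scope_factor,
    emergency_scope_factor = emergency_scope_factor,
    cash_scope_factor = cash_scope_factor,
    programme_support_rate = programme_support_rate,
    capital_build_years = capital_build_years), class = "costing_params")
}

#' Commodity cost of one intervention in one year
#'
#' Persons reached times commodity units times price:
#' `population * target_pop_fraction * in_need_fraction * coverage *
#' units_per_case * commodity_price * unit_price_index`. The incremental
#' variant subtracts the flatline amount.
#'
#' @param country A `country_profile`.
#' @param intervention One catalog row (list or single-row tibble).
#' @param trajectory Coverage trajectory tibble with `year` and `coverage`.
#' @param year Calendar year in 2020-2030.
#' @param flatline_trajectory Optional counterfactual trajectory; when given
#'   the incremental amount (scale-up minus flatline) is returned.
#' @return Cost in US$2014.
#' @export
commodity_cost <- function(country, intervention, trajectory, year,
                           flatline_trajectory = NULL) {
  if (!year %in% phc_horizon()) {
    stop("year must lie in the 2020-2030 investment window", call. = FALSE)
  }
  price <- intervention$commodity_price
  if (is.null(price) || length(price) != 1 || is.na(price)) {
    stop("missing commodity price for intervention ",
         intervention$intervention_id %||% "<unnamed>", call. = FALSE)
  }
  popy <- unname(population_total(country, year))
  amt <- function(tr) {
    cov <- tr$coverage[tr$year == year]
    popy * intervention$target_pop_fraction * intervention$in_need_fraction *
      cov * intervention$units_per_case * price * country$unit_price_index
  }
  out <- amt(trajectory)
  if (!is.null(flatline_trajectory)) out <- out - amt(flatline_trajectory)
  out
}

#' Full-time-equivalent requirement from service minutes
#'
#' @param visit_minutes_total Total service minutes in a year.
#' @param minutes_per_fte_year Available minutes per worker-year (> 0).
#' @return Fractional FTE count (no rounding).
#' @examples
#' fte_requirement(100000 * 19.8, 99000) # 20 FTE
#' @export
fte_requirement <- function(visit_minutes_total, minutes_per_fte_year = 99000) {
  if (any(minutes_per_fte_year <= 0)) {
    stop("minutes_per_fte_year must be positive", call. = FALSE)
  }
  if (any(visit_minutes_total < 0)) {
    stop("service minutes must be non-negative", call. = FALSE)
  }
  visit_minutes_total / minutes_per_fte_year
}

#' PHC workforce requirement and cost via the density-target route
#'
#' The PHC share of bottom-up service minutes (`fte_phc / fte_all_sdg`) is
#' applied to the density-target workforce of the parent full-package
#' projection; the incremental requirement is floored at zero against the
#' current workforce.
#'
#' @param fte_phc Bottom-up FTE requirement of the PHC measure.
#' @param fte_all_sdg Bottom-up FTE requirement of the full package
#'   (must be at least `fte_phc`).
#' @param density_target Target workers per 1000 population.
#' @param population Total population.
#' @param salary Annual cost per FTE (US$).
#' @param current_workers Currently employed workers (for the incremental
#'   floor), default 0.
#' @return A list with `phc_share`, `workforce` (FTE), `workers_per_1000`,
#'   `cost`, and `incremental_workers`.
#' @export
phc_workforce_cost <- function(fte_phc, fte_all_sdg, density_target,
                               population, salary, current_workers = 0) {
  if (fte_phc < 0 || fte_all_sdg < 0 || fte_phc > fte_all_sdg) {
    stop("require 0 <= fte_phc <= fte_all_sdg", call. = FALSE)
  }
  stopifnot(density_target > 0, population > 0, salary >= 0)
  share <- if (fte_all_sdg == 0) 0 else fte_phc / fte_all_sdg
  wf <- share * density_target * population / 1000
  list(phc_share = share,
       workforce = wf,
       workers_per_1000 = 1000 * wf / population,
       cost = wf * salary,
       incremental_workers = max(0, wf - current_workers))
}

#' Allocate facility costs to PHC by level
#'
#' Health centres are attributed in full; district and provincial hospitals
#' carry the measure's shares (33%/3% for the outpatient-core measure,
#' 81%/27% once general inpatient care is included).
#'
#' @param facility_costs Named amounts for `health_centre`,
#'   `district_hospital`, `provincial_hospital` (missing levels allowed).
#' @param measure A [measure_spec()].
#' @return Named amounts scaled by the measure's level shares.
#' @export
infrastructure_cost <- function(facility_costs, measure) {
  stopifnot(inherits(measure, "measure_spec"))
  if (any(facility_costs < 0)) stop("facility costs must be non-negative",
                                    call. = FALSE)
  shares <- c(health_centre = measure$health_centre_share,
              district_hospital = measure$district_hospital_share,
              provincial_hospital = measure$provincial_hospital_share)
  lev <- names(facility_costs)
  if (is.null(lev) || !all(lev %in% names(shares))) {
    stop("facility costs must be named by level", call. = FALSE)
  }
  facility_costs * shares[lev]
}

#' Scope a shared health-system component to a measure
#'
#' Governance and financing scale by the measure's shares; supply chain by
#' the PHC commodity ratio; health information systems by the measure's
#' scope; emergency preparedness by the laboratory-share rule; cash
#' transfers by the care-seeking scope; cold chain, emergency relief and
#' post-conflict reconstruction pass through in full; cross-sectoral
#' investments enter only for the broadest measure.
#'
#' @param component Component name.
#' @param full_amount Full-sector amount (US$, non-negative).
#' @param measure A [measure_spec()].
#' @param commodity_ratio PHC-to-full commodity cost ratio in `[0, 1]`
#'   (required for `supply_chain`).
#' @param params A [costing_params()] (scope factors).
#' @return Scoped amount in US$.
#' @export
shared_system_cost <- function(component, full_amount, measure,
                               commodity_ratio = NULL,
                               params = costing_params()) {
  stopifnot(inherits(measure, "measure_spec"))
  if (full_amount < 0) stop("full_amount must be non-negative", call. = FALSE)
  switch(component,
    governance = full_amount * measure$governance_share,
    financing = full_amount * measure$financing_share,
    supply_chain = {
      if (is.null(commodity_ratio) || is.na(commodity_ratio) ||
          commodity_ratio < 0 || commodity_ratio > 1) {
        stop("supply_chain needs a commodity_ratio in [0, 1]", call. = FALSE)
      }
      full_amount * commodity_ratio
    },
    cold_chain = full_amount,
    emergency_relief = full_amount,
    post_conflict_reconstruction = full_amount,
    his = full_amount * unname(params$his_scope_factor[measure$his_scope]),
    emergency = full_amount *
      unname(params$emergency_scope_factor[measure$emergency_scope]),
    cash_transfers = full_amount *
      unname(params$cash_scope_factor[measure$cash_transfer_scope]),
    cross_sectoral = if (measure$includes_cross_sectoral) full_amount else 0,
    stop("unknown shared system component: ", component, call. = FALSE)
  )
}

#' Redistribute early capital into the investment window
#'
#' Capital amounts in the source years are moved, uniformly per target year,
#' into the investment window; recurrent items are untouched and total
#' capital is conserved exactly.
#'
#' @param ledger Cost ledger tibble (`country_id`, `year`, `measure_id`,
#'   `component`, `cost_type`, `amount`).
#' @param source_years Years whose capital moves (default 2016-2019).
#' @param target_years Receiving years (default 2020-2030).
#' @return The redistributed ledger.
#' @export
redistribute_capital <- function(ledger, source_years = 2016:2019,
                                 target_years = 2020:2030) {
  if (length(intersect(source_years, target_years)) > 0) {
    stop("source and target years must not overlap", call. = FALSE)
  }
  is_src <- ledger$cost_type == "capital" & ledger$year %in% source_years
  if (!any(is_src)) return(ledger)
  moved <- ledger[is_src, ] |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("country_id", "measure_id", "component", "cost_type")))) |>
    dplyr::summarise(amount = sum(.data$amount), .groups = "drop") |>
    tidyr::expand_grid(year = target_years) |>
    dplyr::mutate(amount = .data$amount / length(target_years))
  dplyr::bind_rows(ledger[!is_src, ], moved) |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("country_id", "year", "measure_id", "component", "cost_type")))) |>
    dplyr::summarise(amount = sum(.data$amount), .groups = "drop")
}

#' Aggregate a cost ledger
#'
#' Grouped sums over any ledger columns, with optional per-capita division
#' and annual averaging over the 11-year investment window.
#'
#' @param ledger Cost ledger tibble.
#' @param ... Grouping columns (tidy-select style, e.g. `measure_id`,
#'   `component`).
#' @param population Optional population for per-capita values.
#' @param annual_average If `TRUE`, divide totals by the number of horizon
#'   years (11).
#' @return Tibble of grouped totals (`amount`, plus `amount_per_capita` when
#'   population is given).
#' @export
aggregate_costs <- function(ledger, ..., population = NULL,
                            annual_average = FALSE) {
  out <- ledger |>
    dplyr::group_by(...) |>
    dplyr::summarise(amount = sum(.data$amount), .groups = "drop")
  if (annual_average) out$amount <- out$amount / length(phc_horizon())
  if (!is.null(population)) out$amount_per_capita <- out$amount / population
  out
}

#' Incremental PHC cost ledger for one country and measure
#'
#' Runs the full ingredients engine: incremental commodity and equipment
#' costs from persons reached, bottom-up incremental workforce cost from
#' service minutes, facility capital (modelled over the 2016-2030 build-out
#' then redistributed into 2020-2030) and maintenance with measure-specific
#' hospital shares, scoped shared-system components, and the programme
#' support markup. All amounts are incremental to the flatline counterfactual
#' in US$2014.
#'
#' @param country A `country_profile`.
#' @param catalog Full intervention catalog (the measure subset is selected
#'   internally; full-package totals feed the workforce share and commodity
#'   ratio).
#' @param measure A [measure_spec()] or measure id.
#' @param params A [costing_params()].
#' @return A ledger tibble (`country_id`, `year` in 2020-2030, `measure_id`,
#'   `component`, `cost_type`, `amount`).
#' @export
cost_country <- function(country, catalog, measure, params = costing_params()) {
  if (!inherits(measure, "measure_spec")) measure <- measure_spec(measure)
  years <- phc_years()
  horizon <- phc_horizon()
  popy <- population_total(country)
  idx <- country$unit_price_index
  sub <- catalog[[measure$measure_id]]

  base <- country$baseline_coverage$coverage[
    match(catalog$intervention_id, country$baseline_coverage$intervention_id)]
  if (anyNA(base)) stop("baseline coverage missing for some interventions",
                        call. = FALSE)
  S <- coverage_matrix(base, country$maturity, scaleup = TRUE)
  F <- coverage_matrix(base, country$maturity, scaleup = FALSE)

  tpf <- catalog$target_pop_fraction * catalog$in_need_fraction
  reach <- function(M) M * tpf * rep(popy, each = nrow(catalog))
  Rsu <- reach(S)
  Rfl <- reach(F)
  dR <- pmax(Rsu - Rfl, 0)

  unit_cost <- catalog$units_per_case * catalog$commodity_price * idx
  commodity_inc <- dR * unit_cost                     # intervention x year
  com_inc_meas <- colSums(commodity_inc[sub, , drop = FALSE])
  cap_split <- colSums((commodity_inc * catalog$capital_share)[sub, , drop = FALSE])

  # supply-chain commodity ratio: PHC commodity cost over full-package cost
  com_total_full <- colSums(Rsu * unit_cost)
  com_total_meas <- colSums((Rsu * unit_cost)[sub, , drop = FALSE])
  com_ratio <- ifelse(com_total_full > 0, com_total_meas / com_total_full, 0)

  # bottom-up incremental workforce from service minutes
  minutes <- function(M) M * catalog$visits_per_case * catalog$minutes_per_visit
  Msu <- minutes(Rsu)
  Mfl <- minutes(Rfl)
  fte_su <- fte_requirement(colSums(Msu[sub, , drop = FALSE]),
                            params$minutes_per_fte_year)
  fte_fl <- fte_requirement(colSums(Mfl[sub, , drop = FALSE]),
                            params$minutes_per_fte_year)
  wf_cost <- pmax(fte_su - fte_fl, 0) * params$salary_per_fte * idx

  # facility capital: per-capita reference times mean coverage gain, spread
  # over the build-out years, with measure-specific level shares
  gain_mean <- mean(pmax(0, S[, as.character(2030)] - base))
  build <- params$capital_build_years
  lev_share <- infrastructure_cost(
    c(health_centre = 1, district_hospital = 1, provincial_hospital = 1),
    measure)
  infra_rate <- sum(params$infra_capital_pc * lev_share)
  equip_rate <- sum(params$equipment_capital_pc * lev_share)
  pop_build <- unname(population_total(country, build))
  infra_cap <- infra_rate * pop_build * idx * gain_mean / length(build)
  equip_cap <- equip_rate * pop_build * idx * gain_mean / length(build)

  # shared-system envelopes scale with the year's mean coverage increment
  dbar <- colMeans(pmax(S - F, 0))
  hy <- as.character(horizon)
  env <- function(comp) params$shared_pc[[comp]] * unname(popy[hy]) * idx * dbar[hy]
  shared <- list(
    supply_chain = vapply(seq_along(hy), function(j)
      shared_system_cost("supply_chain", env("supply_chain")[j], measure,
                         commodity_ratio = com_ratio[hy][j], params = params),
      numeric(1)),
    cold_chain = shared_system_cost_vec("cold_chain", env("cold_chain"),
                                        measure, params),
    his = shared_system_cost_vec("his", env("his"), measure, params),
    governance = shared_system_cost_vec("governance", env("governance"),
                                        measure, params),
    financing = shared_system_cost_vec("financing", env("financing"),
                                       measure, params),
    emergency = shared_system_cost_vec("emergency", env("emergency"),
                                       measure, params),
    cash_transfers = shared_system_cost_vec("cash_transfers",
                                            env("cash_transfers"),
                                            measure, params),
    cross_sectoral = shared_system_cost_vec("cross_sectoral",
                                            env("cross_sectoral"),
                                            measure, params))

  prog_support <- params$programme_support_rate *
    (com_inc_meas[hy] + wf_cost[hy])

  row_block <- function(component, cost_type, year, amount) tibble::tibble(
    country_id = country$country_id, year = as.integer(year),
    measure_id = measure$measure_id, component = component,
    cost_type = cost_type, amount = unname(amount))

  ledger <- dplyr::bind_rows(
    row_block("commodities", "recurrent", horizon,
              (com_inc_meas - cap_split)[hy]),
    row_block("equipment", "capital", horizon, cap_split[hy]),
    row_block("workforce", "recurrent", horizon, wf_cost[hy]),
    row_block("infrastructure", "capital", build, infra_cap),
    row_block("equipment", "capital", build, equip_cap),
    row_block("infrastructure", "recurrent", horizon,
              params$maintenance_frac * infra_rate *
                unname(popy[hy]) * idx * dbar[hy] / length(build)),
    purrr::imap_dfr(shared, function(am, comp)
      row_block(comp, "recurrent", horizon, am)),
    row_block("programme_support", "recurrent", horizon, prog_support)
  )
  ledger <- redistribute_capital(ledger, source_years = setdiff(build, horizon),
                                 target_years = horizon)
  ledger[ledger$year %in% horizon, ]
}

# vectorised convenience wrapper over shared_system_cost
shared_system_cost_vec <- function(component, amounts, measure, params) {
  vapply(amounts, function(a)
    shared_system_cost(component, a, measure, params = params), numeric(1))
}

#' Workforce and visit guide posts for one country and measure
#'
#' Applies the density-target workforce model: the PHC share of bottom-up
#' service minutes within the full package, applied to the density-target
#' workforce, yields the PHC workers-per-1000 requirement; outpatient visits
#' combine the baseline contact rate with the modelled incremental visits.
#'
#' @inheritParams cost_country
#' @return One-row tibble for 2030: `phc_share`, `workers_per_1000_current`,
#'   `workers_per_1000_2030`, `visits_per_capita_2030`,
#'   `visits_per_capita_incremental`.
#' @export
workforce_guidepost <- function(country, catalog, measure,
                                params = costing_params()) {
  if (!inherits(measure, "measure_spec")) measure <- measure_spec(measure)
  sub <- catalog[[measure$measure_id]]
  base <- country$baseline_coverage$coverage[
    match(catalog$intervention_id, country$baseline_coverage$intervention_id)]
  popy <- population_total(country)
  y30 <- as.character(2030)
  S <- coverage_matrix(base, country$maturity, scaleup = TRUE)
  F <- coverage_matrix(base, country$maturity, scaleup = FALSE)
  tpf <- catalog$target_pop_fraction * catalog$in_need_fraction
  reach30 <- function(M) M[, y30] * tpf * unname(popy[y30])
  mins <- function(r) sum((r * catalog$visits_per_case *
                             catalog$minutes_per_visit)[sub])
  mins_all <- function(r) sum(r * catalog$visits_per_case *
                                catalog$minutes_per_visit)
  r_su <- reach30(S)
  fte_phc <- fte_requirement(mins(r_su), params$minutes_per_fte_year)
  fte_all <- fte_requirement(mins_all(r_su), params$minutes_per_fte_year)
  cur <- sum(country$workforce_density) * unname(popy[y30]) / 1000
  wf <- phc_workforce_cost(fte_phc, fte_all, params$density_target,
                           unname(popy[y30]),
                           params$salary_per_fte * country$unit_price_index,
                           current_workers = cur)
  visits_su <- sum((r_su * catalog$visits_per_case)[sub]) / unname(popy[y30])
  visits_fl <- sum((reach30(F) * catalog$visits_per_case)[sub]) /
    unname(popy[y30])
  tibble::tibble(
    country_id = country$country_id,
    measure_id = measure$measure_id,
    phc_share = wf$phc_share,
    workers_per_1000_current = sum(country$workforce_density),
    # the requirement never falls below the existing workforce (no shedding)
    workers_per_1000_2030 = pmax(sum(country$workforce_density),
                                 wf$workers_per_1000),
    visits_per_capita_2030 = country$baseline_visits_per_capita +
      (visits_su - visits_fl),
    visits_per_capita_incremental = visits_su - visits_fl)
}
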