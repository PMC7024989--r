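# Investment guide posts: population-weighted aggregation of costs,
# workforce, visits and impact by country group, plus the full pipeline
# driver.

#' Population-weighted mean
#'
#' @param values Per-country amounts.
#' @param weights Populations (strictly positive, same length).
#' @return `sum(values * weights) / sum(weights)`; lies within the range of
#'   `values`.
#' @export
weighted_mean_pop <- function(values, weights) {
  if (!length(values)) stop("empty input", call. = FALSE)
  if (length(weights) != length(values) || any(weights <= 0)) {
    stop("weights must be positive and match values", call. = FALSE)
  }
  sum(values * weights) / sum(weights)
}

#' Total PHC guide post: current plus additional per-capita spending
#'
#' @param current_per_capita Current recurrent PHC expenditure per capita.
#' @param additional_per_capita Additional recurrent PHC cost per capita.
#' @return The exact sum.
#' @examples
#' guidepost_total(25, 40) # 65: low-income recurrent spending doubles+
#' @export
guidepost_total <- function(current_per_capita, additional_per_capita) {
  if (any(current_per_capita < 0) || any(additional_per_capita < 0)) {
    stop("per-capita amounts must be non-negative", call. = FALSE)
  }
  current_per_capita + additional_per_capita
}

#' Deflate to base-year US$
#'
#' @param amount Amount in the stated year's US$.
#' @param deflator Country-specific price deflator (index ratio, > 0).
#' @return `amount / deflator` in US$2014.
#' @export
deflate <- function(amount, deflator) {
  if (any(deflator <= 0)) stop("deflator must be positive", call. = FALSE)
  amount / deflator
}

#' Percentage of a reference value
#'
#' @param value Numerator count.
#' @param reference Reference count (> 0).
#' @return Integer percent, rounded half-up.
#' @examples
#' proportion_of_reference(60.1, 89) # 68
#' @export
proportion_of_reference <- function(value, reference) {
  if (any(reference <= 0)) stop("reference must be positive", call. = FALSE)
  round_half_up(100 * value / reference)
}

#' Pipeline configuration
#'
#' @param n_countries,seed,n_interventions Passed to [generator_config()].
#' @param measures Measures to run (default all three).
#' @param scenarios Financing scenarios to run (default all three).
#' @param weight_year Population year used as aggregation weight (default
#'   2020, the first investment year).
#' @param gap_measure Measure whose costs feed the financing-gap analysis.
#' @param phc_allocation Share of incremental health funds countable against
#'   PHC (see [funding_gap()]).
#' @param costing A [costing_params()].
#' @param generator Optional pre-built [generator_config()] overriding the
#'   scalar arguments.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_countries = 67L, seed = 1L,
                            n_interventions = 188L,
                            measures = c("m1", "m2", "m3"),
                            scenarios = c("bau", "progress1", "ambitious2"),
                            weight_year = 2020L, gap_measure = "m1",
                            phc_allocation = 1,
                            costing = costing_params(),
                            generator = NULL) {
  stopifnot(all(measures %in% c("m1", "m2", "m3")),
            all(scenarios %in% phc_scenarios()),
            gap_measure %in% measures)
  gen <- generator %||% generator_config(n_countries = n_countries,
                                         seed = seed,
                                         n_interventions = n_interventions)
  structure(list(generator = gen, measures = measures, scenarios = scenarios,
                 weight_year = as.integer(weight_year),
                 gap_measure = gap_measure, phc_allocation = phc_allocation,
                 costing = costing, seed = gen$seed),
            class = "pipeline_config")
}

#' Run the full projection pipeline
#'
#' Generates (or accepts) the country cohort and catalog, builds coverage
#' trajectories, runs the cost engine and the impact model for every measure,
#' projects financing under every scenario, and assembles the guide-post
#' report by income group, maturity category and overall. Identical
#' configurations produce identical output.
#'
#' @param config A [pipeline_config()].
#' @param countries Optional pre-built list of `country_profile` objects.
#' @param catalog Optional pre-built catalog.
#' @param out_dir Optional directory; when given, all result tables are
#'   written as tab-delimited text plus a small JSON run manifest.
#' @return A list: `countries` (summary tibble), `ledger`, `cost_totals`,
#'   `guideposts`, `impact_totals`, `hly`, `financing`, `gap_counts`,
#'   `workforce`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), countries = NULL,
                         catalog = NULL, out_dir = NULL) {
  t0 <- Sys.time()
  stage <- function(msg) message(sprintf("[%5.1fs] %s",
    as.numeric(difftime(Sys.time(), t0, units = "secs")), msg))

  if (is.null(catalog)) {
    catalog <- generate_catalog(config$generator$n_interventions,
                                seed = config$generator$seed)
  }
  if (is.null(countries)) {
    stage("generating country profiles")
    countries <- generate_countries(config$generator, catalog = catalog)
  }
  summary_tab <- country_summary(countries)

  stage("costing")
  ledger <- purrr::map_dfr(countries, function(co) {
    purrr::map_dfr(config$measures, function(m) {
      cost_country(co, catalog, m, config$costing)
    })
  })

  stage("workforce and visit guide posts")
  workforce <- purrr::map_dfr(countries, function(co) {
    purrr::map_dfr(config$measures, function(m) {
      workforce_guidepost(co, catalog, m, config$costing)
    })
  })

  stage("impact projection")
  impacts <- purrr::map(countries, function(co) {
    purrr::map(config$measures, function(m) {
      impact_country(co, catalog, m, config$costing)
    })
  })
  impact_totals <- purrr::map_dfr(impacts, function(by_m) {
    purrr::map_dfr(by_m, function(im) {
      dplyr::mutate(im$totals, country_id = im$country_id,
                    measure_id = im$measure_id, .before = 1)
    })
  })
  le_tab <- purrr::map_dfr(impacts, function(by_m) {
    purrr::map_dfr(by_m, function(im) tibble::tibble(
      country_id = im$country_id, measure_id = im$measure_id,
      le_gain = im$le$gain_vs_2015))
  })
  hly_tab <- purrr::map_dfr(impacts, function(by_m) {
    purrr::map_dfr(by_m, function(im) dplyr::mutate(
      im$hly, country_id = im$country_id, measure_id = im$measure_id,
      .before = 1))
  })

  stage("financing scenarios")
  financing <- purrr::map_dfr(countries, function(co) {
    purrr::map_dfr(config$scenarios, function(sc) project_che(co, sc))
  })
  gap_costs <- ledger[ledger$measure_id == config$gap_measure, ]
  gap_counts <- purrr::map_dfr(config$scenarios, function(sc) {
    projs <- split(financing[financing$scenario == sc, ],
                   financing$country_id[financing$scenario == sc])
    tibble::tibble(scenario = sc, year = 2030L,
                   n_gap = count_gap_countries(projs, gap_costs, 2030,
                                               config$phc_allocation),
                   n_countries = length(countries))
  })

  stage("guide-post report")
  guideposts <- purrr::map_dfr(config$measures, function(m) {
    guidepost_report(countries, ledger, workforce, impact_totals, le_tab,
                     measure = m, weight_year = config$weight_year)
  })

  cost_totals <- ledger |>
    dplyr::group_by(.data$measure_id, .data$component, .data$cost_type) |>
    dplyr::summarise(amount = sum(.data$amount), .groups = "drop")

  out <- list(countries = summary_tab, catalog = catalog, ledger = ledger,
              cost_totals = cost_totals, guideposts = guideposts,
              impact_totals = impact_totals, le = le_tab, hly = hly_tab,
              financing = financing, gap_counts = gap_counts,
              workforce = workforce, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, f) utils::write.table(
      df, file.path(out_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
    wr(summary_tab, "countries.tsv")
    wr(ledger, "cost_ledger.tsv")
    wr(cost_totals, "cost_totals.tsv")
    wr(guideposts, "guideposts.tsv")
    wr(impact_totals, "deaths_averted.tsv")
    wr(hly_tab, "healthy_life_years.tsv")
    wr(financing, "financing.tsv")
    wr(gap_counts, "gap_counts.tsv")
    wr(workforce, "workforce.tsv")
    writeLines(paste0("{\"seed\": ", config$seed,
                      ", \"n_countries\": ", config$generator$n_countries,
                      ", \"n_interventions\": ",
                      config$generator$n_interventions, "}"),
               file.path(out_dir, "manifest.json"))
  }
  stage("done")
  out
}

#' Guide-post report for one measure
#'
#' Mirrors the published guide-post table structure: rows per income group,
#' per maturity category and for all countries; per-capita values are
#' population-weighted.
#'
#' @param countries List of `country_profile` objects.
#' @param ledger Cost ledger covering the measure.
#' @param workforce Output of [workforce_guidepost()] rows.
#' @param impact_totals Deaths averted by country and cause.
#' @param le_tab Life-expectancy gains by country.
#' @param measure Measure id.
#' @param weight_year Population year used as weight.
#' @return Tibble, one row per group, with cost, workforce, visit and impact
#'   guide posts. `total_recurrent_per_capita_2030` equals
#'   `current_phc_per_capita + additional_recurrent_per_capita` exactly.
#' @export
guidepost_report <- function(countries, ledger, workforce, impact_totals,
                             le_tab, measure = "m1", weight_year = 2020L) {
  summary_tab <- country_summary(countries)
  popw <- purrr::map_dbl(countries,
    ~ sum(.x$population$pop[.x$population$year == weight_year]))
  names(popw) <- purrr::map_chr(countries, "country_id")

  led <- ledger[ledger$measure_id == measure, ]
  per_country <- led |>
    dplyr::group_by(.data$country_id, .data$cost_type) |>
    dplyr::summarise(amount = sum(.data$amount), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "cost_type", values_from = "amount",
                       values_fill = 0)
  if (!"capital" %in% names(per_country)) per_country$capital <- 0
  per_country$total <- per_country$capital + per_country$recurrent

  wf <- workforce[workforce$measure_id == measure, ]
  av <- impact_totals[impact_totals$measure_id == measure, ] |>
    dplyr::group_by(.data$country_id) |>
    dplyr::summarise(deaths_averted = sum(.data$deaths_averted),
                     .groups = "drop")
  le <- le_tab[le_tab$measure_id == measure, ]

  tab <- summary_tab |>
    dplyr::left_join(per_country, by = "country_id") |>
    dplyr::left_join(wf[, c("country_id", "workers_per_1000_current",
                            "workers_per_1000_2030", "visits_per_capita_2030",
                            "visits_per_capita_incremental")],
                     by = "country_id") |>
    dplyr::left_join(av, by = "country_id") |>
    dplyr::left_join(le[, c("country_id", "le_gain")], by = "country_id")
  tab$pop_w <- unname(popw[tab$country_id])
  ny <- length(phc_horizon())

  one_group <- function(df, label) {
    w <- df$pop_w
    add_rec_pc <- df$recurrent / ny / w
    add_tot_pc <- df$total / ny / w
    cur_pc <- weighted_mean_pop(df$current_phc_exp_per_capita, w)
    rec_pc <- weighted_mean_pop(add_rec_pc, w)
    tibble::tibble(
      group = label,
      measure_id = measure,
      n_countries = nrow(df),
      additional_cost_total = sum(df$total),
      additional_cost_annual = sum(df$total) / ny,
      additional_cost_annual_recurrent = sum(df$recurrent) / ny,
      additional_per_capita = weighted_mean_pop(add_tot_pc, w),
      additional_recurrent_per_capita = rec_pc,
      current_phc_per_capita = cur_pc,
      total_recurrent_per_capita_2030 = guidepost_total(cur_pc, rec_pc),
      workers_per_1000_current = weighted_mean_pop(df$workers_per_1000_current, w),
      workers_per_1000_2030 = weighted_mean_pop(df$workers_per_1000_2030, w),
      visits_per_capita_2030 = weighted_mean_pop(df$visits_per_capita_2030, w),
      visits_per_capita_incremental =
        weighted_mean_pop(df$visits_per_capita_incremental, w),
      deaths_averted_total = sum(df$deaths_averted),
      le_gain_years = weighted_mean_pop(df$le_gain, w))
  }

  rows <- list(one_group(tab, "all"))
  for (g in income_groups()) {
    df <- tab[tab$income_group == g, ]
    if (nrow(df)) rows[[length(rows) + 1]] <- one_group(df, g)
  }
  for (g in maturity_levels()) {
    df <- tab[tab$maturity == g, ]
    if (nrow(df)) rows[[length(rows) + 1]] <- one_group(df, g)
  }
  dplyr::bind_rows(rows)
}
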