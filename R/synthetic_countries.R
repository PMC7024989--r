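# Synthetic country generator.
#
# The study cohort of 67 low- and middle-income countries (with WHO's
# country-level price-tag inputs) is not public. This module generates
# profiles with the statistical structure the downstream stages assume:
# three income groups crossed with five system-maturity categories
# (conflict, vulnerable, and health-system strength 1-3), income-graded
# prices, coverage, workforce density and mortality, and a historical
# health-expenditure series for trend extrapolation.

income_groups <- function() c("low", "lower_middle", "upper_middle")
maturity_levels <- function() c("conflict", "vulnerable", "hs1", "hs2", "hs3")

# Income-group parameter block. Anchors that the published guide-post table
# prints are used directly: current recurrent PHC spending per capita (25 /
# 34 / 304 US$2014), workforce density (1.4 / 4.6 / 7.9 per 1000), baseline
# outpatient visits (2030 totals minus incremental: 1.7 / 1.7 / 5.2), and a
# mean health expenditure share of GDP around 5.6%. The rest are realistic
# LMIC levels chosen once and documented in the methods vignette.
income_params <- function() {
  tibble::tibble(
    income_group   = income_groups(),
    gdp_meanlog    = log(c(700, 2200, 7500)),
    gdp_sdlog      = 0.35,
    gdp_growth     = c(0.030, 0.032, 0.030),
    pop_meanlog    = log(c(1.5e7, 4e7, 3e7)),
    pop_sdlog      = 1.0,
    pop_growth     = c(0.027, 0.015, 0.006),
    pyramid_decay  = c(0.040, 0.028, 0.016),
    che_mean       = c(5.0, 5.5, 6.0),
    che_sd         = 1.0,
    che_slope_mean = 0.05,
    che_slope_sd   = 0.04,
    che_noise_sd   = 0.08,
    phc_exp_mean   = c(25, 34, 304),
    phc_exp_sdlog  = 0.30,
    wf_density_mean = c(1.4, 4.6, 7.9),
    wf_sdlog       = 0.25,
    visits_mean    = c(1.7, 1.7, 5.2),
    price_meanlog  = log(c(0.55, 1.0, 1.7)),
    price_sdlog    = 0.20,
    infant_mx      = c(0.055, 0.030, 0.012),
    child_mx       = c(0.008, 0.004, 0.0015),
    adult_a20      = c(0.0035, 0.0025, 0.0018),
    gompertz_b     = 0.082,
    mort_sdlog     = 0.15,
    stillbirth_mx  = c(0.025, 0.018, 0.012),
    coverage_offset = c(-0.05, 0.00, 0.08)
  )
}

# Mean baseline coverage by system maturity (weaker systems -> lower).
maturity_coverage_means <- function() {
  c(conflict = 0.25, vulnerable = 0.35, hs1 = 0.45, hs2 = 0.55, hs3 = 0.62)
}

#' Configuration for the synthetic country generator
#'
#' @param n_countries Number of countries to generate (study cohort size 67).
#' @param seed Integer RNG seed; identical configurations give bit-identical
#'   output.
#' @param n_interventions Catalog size used for baseline coverage draws when
#'   no catalog is passed to [generate_countries()].
#' @param group_mix Tibble with columns `income_group`, `maturity`, `prop`
#'   giving the sampling proportions over the 15 income-by-maturity cells;
#'   must sum to 1. Default: income split 0.33 / 0.45 / 0.22 with maturity
#'   uniform within income group (the true cohort composition is not
#'   published).
#' @param income_params Per-income-group prior parameters; defaults documented
#'   in the methods vignette. Override columns to change GDP, price, coverage,
#'   or mortality gradients.
#' @param coverage_means Named vector of mean baseline coverage by maturity.
#' @param coverage_concentration Beta concentration (alpha + beta) of the
#'   per-intervention baseline coverage draws.
#' @return A `generator_config` list, validated.
#' @export
generator_config <- function(n_countries = 67L, seed = 1L,
                             n_interventions = 188L, group_mix = NULL,
                             income_params = NULL, coverage_means = NULL,
                             coverage_concentration = 25) {
  if (length(n_countries) != 1 || is.na(n_countries) || n_countries < 1) {
    stop("n_countries must be a positive count", call. = FALSE)
  }
  if (is.null(group_mix)) {
    inc <- c(low = 0.33, lower_middle = 0.45, upper_middle = 0.22)
    group_mix <- tidyr::expand_grid(income_group = income_groups(),
                                    maturity = maturity_levels())
    group_mix$prop <- inc[group_mix$income_group] / 5
  }
  if (!all(c("income_group", "maturity", "prop") %in% names(group_mix)) ||
      any(group_mix$prop < 0) ||
      abs(sum(group_mix$prop) - 1) > 1e-8) {
    stop("group_mix proportions must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (!all(group_mix$income_group %in% income_groups()) ||
      !all(group_mix$maturity %in% maturity_levels())) {
    stop("group_mix uses unknown income or maturity levels", call. = FALSE)
  }
  ip <- income_params %||% income_defaults()
  cm <- coverage_means %||% maturity_coverage_means()
  if (!all(maturity_levels() %in% names(cm))) {
    stop("coverage_means must name every maturity level", call. = FALSE)
  }
  structure(list(n_countries = as.integer(n_countries),
                 seed = as.integer(seed),
                 n_interventions = as.integer(n_interventions),
                 group_mix = group_mix, income_params = ip,
                 coverage_means = cm,
                 coverage_concentration = coverage_concentration),
            class = "generator_config")
}

#' Default income-group prior parameters
#' @return Tibble of per-income-group generator parameters.
#' @export
income_defaults <- function() income_params()

#' Generate synthetic country profiles
#'
#' Draws `n_countries` country profiles under the configured priors. Each
#' profile carries demography by year, abridged age group and sex (2015-2030),
#' GDP per capita, a 2015-2019 health-expenditure history (% of GDP), current
#' recurrent PHC expenditure per capita, workforce densities by cadre,
#' baseline outpatient visits, per-intervention baseline coverage, cause-,
#' age- and sex-specific mortality rates, and a unit price index.
#'
#' Income gradients are built in: lower-income groups draw stochastically
#' lower coverage, prices and workforce density and higher mortality.
#'
#' @param config A [generator_config()].
#' @param catalog Optional intervention catalog whose ids anchor the baseline
#'   coverage table; defaults to `generate_catalog(config$n_interventions,
#'   seed = config$seed)`.
#' @return A list of `country_profile` objects.
#' @export
generate_countries <- function(config = generator_config(), catalog = NULL) {
  if (!inherits(config, "generator_config")) {
    stop("config must be created by generator_config()", call. = FALSE)
  }
  if (is.null(catalog)) {
    catalog <- generate_catalog(config$n_interventions, seed = config$seed)
  }
  ids <- catalog$intervention_id
  ages <- phc_age_groups()
  years <- phc_years()
  ip <- config$income_params
  cm <- config$coverage_means
  conc <- config$coverage_concentration

  withr_seed(config$seed, {
    cells <- sample(nrow(config$group_mix), config$n_countries,
                    replace = TRUE, prob = config$group_mix$prop)
    purrr::map(seq_len(config$n_countries), function(i) {
      cell <- config$group_mix[cells[i], ]
      inc <- cell$income_group
      mat <- cell$maturity
      p <- ip[ip$income_group == inc, ]

      pop0 <- stats::rlnorm(1, p$pop_meanlog, p$pop_sdlog)
      age_mid <- ifelse(is.infinite(ages$n), ages$age_start + 7.5,
                        ages$age_start + ages$n / 2)
      share_age <- exp(-p$pyramid_decay * age_mid) *
        ifelse(is.infinite(ages$n), 5, ages$n)
      share_age <- share_age / sum(share_age)
      pop_tab <- tidyr::expand_grid(year = years,
                                    age_group = ages$age_group,
                                    sex = c("female", "male"))
      pop_tab$pop <- pop0 * (1 + p$pop_growth)^(pop_tab$year - 2015) *
        share_age[match(pop_tab$age_group, ages$age_group)] * 0.5

      gdp0 <- stats::rlnorm(1, p$gdp_meanlog, p$gdp_sdlog)
      gdp_tab <- tibble::tibble(
        year = years,
        gdp_pc = gdp0 * (1 + p$gdp_growth)^(years - 2015))

      che_level <- max(1, stats::rnorm(1, p$che_mean, p$che_sd))
      che_slope <- stats::rnorm(1, p$che_slope_mean, p$che_slope_sd)
      hist_years <- 2015:2019
      che_tab <- tibble::tibble(
        year = hist_years,
        che_pct = pmin(24, pmax(0.5,
          che_level + che_slope * (hist_years - 2017) +
            stats::rnorm(length(hist_years), 0, p$che_noise_sd))))

      wf_total <- stats::rlnorm(1, log(p$wf_density_mean), p$wf_sdlog)
      wf <- c(doctor = 0.15, nurse_midwife = 0.45, other = 0.40) * wf_total

      mu <- min(0.85, max(0.05, unname(cm[mat]) + p$coverage_offset))
      cov <- stats::rbeta(length(ids), mu * conc, (1 - mu) * conc)
      cov <- pmin(0.92, pmax(0.01, cov))

      mort_mult <- stats::rlnorm(1, 0, p$mort_sdlog)
      mx_total <- function(age_start, sex) {
        base <- ifelse(age_start < 1, p$infant_mx,
                ifelse(age_start < 5, p$child_mx,
                       p$adult_a20 * exp(p$gompertz_b * (pmax(age_start + 2.5, 5) - 20))))
        sexf <- ifelse(sex == "male", 1.1, 0.9)
        pmin(0.7, base * sexf * mort_mult)
      }
      mort <- tidyr::expand_grid(age_group = ages$age_group,
                                 sex = c("female", "male"))
      mort$age_start <- ages$age_start[match(mort$age_group, ages$age_group)]
      mort$total_mx <- mx_total(mort$age_start, mort$sex)
      mort_rows <- purrr::pmap(mort, function(age_group, sex, age_start, total_mx) {
        alloc <- cause_allocation(age_start, sex)
        tibble::tibble(age_group = age_group, sex = sex,
                       cause_group = names(alloc), mx = total_mx * alloc)
      })
      mortality <- dplyr::bind_rows(mort_rows)
      mortality <- mortality[mortality$mx > 0 | mortality$cause_group == "other", ]
      stillb <- tibble::tibble(
        age_group = "0", sex = c("female", "male"),
        cause_group = "stillbirth",
        mx = p$stillbirth_mx * mort_mult)
      mortality <- dplyr::bind_rows(mortality, stillb)

      structure(list(
        country_id = sprintf("C%03d", i),
        income_group = inc,
        maturity = mat,
        population = pop_tab,
        gdp_per_capita = gdp_tab,
        che_pct_gdp = che_tab,
        current_phc_exp_per_capita = stats::rlnorm(1, log(p$phc_exp_mean),
                                                   p$phc_exp_sdlog),
        workforce_density = wf,
        baseline_visits_per_capita = max(0.2, stats::rnorm(1, p$visits_mean, 0.4)),
        baseline_coverage = tibble::tibble(intervention_id = ids,
                                           coverage = cov),
        mortality_rate = mortality,
        unit_price_index = stats::rlnorm(1, p$price_meanlog, p$price_sdlog)
      ), class = "country_profile")
    })
  })
}

#' Total population of a country in a year
#' @param country A `country_profile`.
#' @param year Calendar year (defaults to all model years).
#' @return Named numeric vector of total population by year.
#' @export
population_total <- function(country, year = phc_years()) {
  p <- country$population
  out <- vapply(year, function(y) sum(p$pop[p$year == y]), numeric(1))
  stats::setNames(out, year)
}

#' Validate a country profile against its invariants
#'
#' @param country A `country_profile`.
#' @return Tibble of violations (`field`, `message`); zero rows when valid.
#' @export
validate_country_profile <- function(country) {
  v <- list()
  bad <- function(cond, field, msg) {
    if (isTRUE(cond)) v[[length(v) + 1]] <<- tibble::tibble(field = field,
                                                            message = msg)
  }
  bad(any(country$population$pop <= 0), "population", "non-positive population")
  bad(any(country$che_pct_gdp$che_pct <= 0 | country$che_pct_gdp$che_pct >= 25),
      "che_pct_gdp", "outside (0, 25)")
  bad(any(country$baseline_coverage$coverage < 0 |
            country$baseline_coverage$coverage > 1),
      "baseline_coverage", "outside [0, 1]")
  bad(any(country$mortality_rate$mx < 0), "mortality_rate", "negative rate")
  bad(!(country$unit_price_index > 0), "unit_price_index", "not positive")
  bad(!country$income_group %in% income_groups(), "income_group",
      "unknown level")
  bad(!country$maturity %in% maturity_levels(), "maturity", "unknown level")
  if (length(v)) dplyr::bind_rows(v)
  else tibble::tibble(field = character(), message = character())
}

#' One-row-per-country scalar summary
#' @param countries List of `country_profile` objects.
#' @return Tibble with identifiers, grouping variables and scalar fields.
#' @export
country_summary <- function(countries) {
  purrr::map_dfr(countries, function(co) {
    tibble::tibble(
      country_id = co$country_id,
      income_group = co$income_group,
      maturity = co$maturity,
      pop_2020 = sum(co$population$pop[co$population$year == 2020]),
      gdp_pc_2020 = co$gdp_per_capita$gdp_pc[co$gdp_per_capita$year == 2020],
      che_pct_2019 = co$che_pct_gdp$che_pct[co$che_pct_gdp$year == 2019],
      current_phc_exp_per_capita = co$current_phc_exp_per_capita,
      workforce_per_1000 = sum(co$workforce_density),
      baseline_visits_per_capita = co$baseline_visits_per_capita,
      unit_price_index = co$unit_price_index,
      mean_baseline_coverage = mean(co$baseline_coverage$coverage)
    )
  })
}

#' Write country profiles as tidy delimited tables
#'
#' Emits `countries.tsv` (scalars), `demography.tsv` (country-year-age-sex),
#' `coverage_baseline.tsv`, `mortality.tsv` and a `manifest.json` recording
#' the generator configuration.
#'
#' @param countries List of `country_profile` objects.
#' @param dir Output directory (created if needed).
#' @param config Optional `generator_config` recorded in the manifest.
#' @return Invisibly, the directory path.
#' @export
write_country_tables <- function(countries, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  wr(country_summary(countries), "countries.tsv")
  wr(purrr::map_dfr(countries,
       ~ dplyr::mutate(.x$population, country_id = .x$country_id,
                       .before = 1)), "demography.tsv")
  wr(purrr::map_dfr(countries,
       ~ dplyr::mutate(.x$baseline_coverage, country_id = .x$country_id,
                       .before = 1)), "coverage_baseline.tsv")
  wr(purrr::map_dfr(countries,
       ~ dplyr::mutate(.x$mortality_rate, country_id = .x$country_id,
                       .before = 1)), "mortality.tsv")
  if (!is.null(config)) {
    man <- list(n_countries = config$n_countries, seed = config$seed,
                n_interventions = config$n_interventions)
    writeLines(paste0("{\"n_countries\": ", man$n_countries,
                      ", \"seed\": ", man$seed,
                      ", \"n_interventions\": ", man$n_interventions, "}"),
               file.path(dir, "manifest.json"))
  }
  invisible(dir)
}
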