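# Coverage trajectories 2015-2030: maturity-differentiated linear scale-up
# after 2019 (limited progress is assumed over 2015-19) and the flatline
# counterfactual of unchanged coverage.

#' Default 2030 coverage targets by system maturity
#'
#' Stronger systems are assumed able to reach higher 2030 coverage. The
#' published framework states differentiated scale-up speed without printing
#' the functional form or endpoints; these defaults are config-exposed.
#'
#' @return Named numeric vector of 2030 targets.
#' @export
maturity_targets <- function() {
  c(conflict = 0.70, vulnerable = 0.80, hs1 = 0.85, hs2 = 0.90, hs3 = 0.95)
}

#' Build a coverage scale-up trajectory
#'
#' Coverage holds at the baseline through `start_year` (default 2019), then
#' rises linearly to the maturity-specific 2030 target. Coverage is never
#' scaled down: a baseline at or above the target stays flat.
#'
#' @param baseline Baseline coverage in `[0, 1]`.
#' @param maturity Maturity level (one of `conflict`, `vulnerable`, `hs1`,
#'   `hs2`, `hs3`), used to look up the target unless `target` is given.
#' @param start_year Last year at baseline (default 2019).
#' @param end_year Year the target is reached (default 2030).
#' @param target Optional explicit 2030 target overriding the maturity lookup.
#' @return A tibble with columns `year`, `coverage`, `counterfactual`
#'   (`FALSE` for scale-up).
#' @examples
#' tr <- build_trajectory(0.25, "hs1", target = 0.80)
#' tr$coverage[tr$year == 2025] # 0.55, six of eleven steps
#' @export
build_trajectory <- function(baseline, maturity = "hs1", start_year = 2019,
                             end_year = 2030, target = NULL) {
  if (length(baseline) != 1 || is.na(baseline) || baseline < 0 || baseline > 1) {
    stop("baseline coverage must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(target)) {
    tg <- maturity_targets()
    if (!maturity %in% names(tg)) {
      stop("unknown maturity level: ", maturity, call. = FALSE)
    }
    target <- unname(tg[maturity])
  }
  years <- phc_years()
  cov <- rep(baseline, length(years))
  if (target > baseline) {
    ramp <- years > start_year
    frac <- pmin(1, (years[ramp] - start_year) / (end_year - start_year))
    cov[ramp] <- baseline + frac * (target - baseline)
  }
  tibble::tibble(year = years, coverage = cov, counterfactual = FALSE)
}

#' Flatline counterfactual trajectory
#'
#' Coverage unchanged from baseline in every year.
#'
#' @inheritParams build_trajectory
#' @return A tibble with columns `year`, `coverage`, `counterfactual = TRUE`.
#' @export
flatline <- function(baseline) {
  if (length(baseline) != 1 || is.na(baseline) || baseline < 0 || baseline > 1) {
    stop("baseline coverage must lie in [0, 1]", call. = FALSE)
  }
  tibble::tibble(year = phc_years(), coverage = baseline,
                 counterfactual = TRUE)
}

# Vectorised scale-up coverage for a whole catalog: interventions x years
# matrix under the country's maturity target (rows follow `baselines`).
coverage_matrix <- function(baselines, maturity, scaleup = TRUE,
                            start_year = 2019, end_year = 2030) {
  years <- phc_years()
  tg <- unname(maturity_targets()[maturity])
  base <- matrix(baselines, nrow = length(baselines), ncol = length(years))
  if (!scaleup) {
    colnames(base) <- years
    return(base)
  }
  frac <- pmax(0, pmin(1, (years - start_year) / (end_year - start_year)))
  gain <- pmax(0, tg - baselines)
  out <- base + outer(gain, frac)
  colnames(out) <- years
  out
}

#' Tidy coverage trajectories for one country
#'
#' @param country A `country_profile`.
#' @param catalog Intervention catalog aligned with the country's baseline
#'   coverage table.
#' @return Tibble `country_id`, `intervention_id`, `year`, `coverage`,
#'   `counterfactual`, covering both the scale-up and the flatline scenario.
#' @export
coverage_table <- function(country, catalog) {
  base <- country$baseline_coverage$coverage[
    match(catalog$intervention_id, country$baseline_coverage$intervention_id)]
  years <- phc_years()
  su <- coverage_matrix(base, country$maturity, scaleup = TRUE)
  fl <- coverage_matrix(base, country$maturity, scaleup = FALSE)
  mk <- function(m, cf) tibble::tibble(
    country_id = country$country_id,
    intervention_id = rep(catalog$intervention_id, times = length(years)),
    year = rep(years, each = nrow(catalog)),
    coverage = as.vector(m),
    counterfactual = cf)
  dplyr::bind_rows(mk(su, FALSE), mk(fl, TRUE))
}
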