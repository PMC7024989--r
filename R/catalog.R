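# Intervention catalog and the three nested PHC measure definitions.
#
# The published model works from 188 essential health interventions of which
# 143 / 152 / 160 fall under PHC measures 1 / 2 / 3 (nested). The full
# intervention list is not public, so the packaged catalog is synthetic: the
# printed counts, platform taxonomy and the named example interventions are
# respected, while per-intervention resource and effectiveness parameters are
# drawn from seeded distributions and are user-overridable.

phc_platforms <- function() {
  c("policy_population", "outreach", "first_level_clinical",
    "first_level_and_above", "cross_sectoral")
}

#' Measure specification (health-system allocation rules)
#'
#' Returns the allocation-share rule set attached to one of the three nested
#' PHC measures:
#' * `m1` - preventive and outpatient core: district/provincial hospital
#'   shares 33%/3%, governance and financing at 80%, facility-based health
#'   information systems only, laboratory share of emergency preparedness,
#'   no cash transfers.
#' * `m2` - adds general inpatient care: hospital shares rise to 81%/27%,
#'   governance/financing at 100%, full-sector information systems, full
#'   emergency preparedness, cash transfers for skilled birth attendance.
#' * `m3` - as `m2` plus census/civil-registry information systems, general
#'   care-seeking cash transfers and cross-sectoral investments.
#'
#' Health-centre costs are attributed in full under every measure; cold
#' chain, emergency relief and post-conflict reconstruction likewise.
#'
#' @param measure_id One of `"m1"`, `"m2"`, `"m3"`.
#' @return An object of class `measure_spec`.
#' @export
measure_spec <- function(measure_id = c("m1", "m2", "m3")) {
  measure_id <- match.arg(measure_id)
  base <- switch(measure_id,
    m1 = list(district_hospital_share = 0.33, provincial_hospital_share = 0.03,
              governance_share = 0.80, financing_share = 0.80,
              his_scope = "facility_only", emergency_scope = "lab_share_only",
              cash_transfer_scope = "none", includes_cross_sectoral = FALSE),
    m2 = list(district_hospital_share = 0.81, provincial_hospital_share = 0.27,
              governance_share = 1.00, financing_share = 1.00,
              his_scope = "full_sector", emergency_scope = "full_preparedness",
              cash_transfer_scope = "birth_only",
              includes_cross_sectoral = FALSE),
    m3 = list(district_hospital_share = 0.81, provincial_hospital_share = 0.27,
              governance_share = 1.00, financing_share = 1.00,
              his_scope = "full_sector_plus_census",
              emergency_scope = "full_preparedness",
              cash_transfer_scope = "general", includes_cross_sectoral = TRUE)
  )
  structure(c(list(measure_id = measure_id, health_centre_share = 1.0), base),
            class = "measure_spec")
}

# Named example interventions kept verbatim in the default catalog, with the
# measure block they belong to ("m1" = in all three, "m2" = added at measure
# 2, "m3" = added at measure 3).
named_interventions <- function() {
  tibble::tribble(
    ~name,                                          ~platform,               ~block, ~cause_group,
    "Taxes on alcohol and tobacco",                 "policy_population",      "m1",  "ncd",
    "Breastfeeding promotion campaign",             "policy_population",      "m1",  "post_neonatal",
    "Safe-sex behaviour change communication",      "policy_population",      "m1",  "hiv",
    "Childhood vaccination programme",              "outreach",               "m1",  "post_neonatal",
    "Family planning",                              "outreach",               "m1",  "maternal",
    "Micronutrient supplementation",                "outreach",               "m1",  "post_neonatal",
    "Oral antibiotics for pneumonia",               "first_level_clinical",   "m1",  "post_neonatal",
    "First-line tuberculosis treatment",            "first_level_clinical",   "m1",  "tb",
    "Glycaemic control for diabetes",               "first_level_clinical",   "m1",  "ncd",
    "Smoking cessation counselling",                "first_level_clinical",   "m1",  "ncd",
    "Antiretroviral therapy",                       "first_level_clinical",   "m1",  "hiv",
    "Cervical cancer screening",                    "first_level_clinical",   "m1",  "cancer",
    "Mass drug administration for NTDs",            "outreach",               "m1",  "ntd",
    "Mammography to detect breast cancer",          "first_level_and_above",  "m1",  "cancer",
    "Treatment of asthma and COPD",                 "first_level_and_above",  "m1",  "ncd",
    "Normal delivery care",                         "first_level_clinical",   "m2",  "neonatal",
    "Basic neonate resuscitation",                  "first_level_clinical",   "m2",  "neonatal",
    "Basic emergency obstetric care",               "first_level_and_above",  "m2",  "maternal",
    "Water and sanitation",                         "cross_sectoral",         "m3",  "post_neonatal",
    "Hygiene promotion",                            "cross_sectoral",         "m3",  "post_neonatal",
    "Food safety",                                  "cross_sectoral",         "m3",  "other"
  )
}

#' Generate a synthetic intervention catalog
#'
#' Builds an intervention table with nested measure membership: the first
#' `m_counts[1]` interventions carry all three measure flags, the next block
#' is added at measure 2, the next at measure 3, and the remainder
#' (specialised care) falls outside PHC. Named example interventions from the
#' published measure definitions are embedded verbatim when they fit the
#' requested sizes; all resource and effectiveness parameters are drawn from
#' seeded distributions.
#'
#' @param n_interventions Total number of interventions (default 188).
#' @param seed Integer RNG seed.
#' @param m_counts Measure sizes `c(m1, m2, m3)`; must be non-decreasing and
#'   at most `n_interventions`. Defaults to `c(143, 152, 160)` for the
#'   188-item catalog and to the proportionally scaled (rounded) sizes for
#'   other catalog sizes.
#' @return A tibble with one row per intervention: identifiers, platform,
#'   logical flags `m1`/`m2`/`m3`, target population and need fractions,
#'   commodity units and reference prices (US$2014), visit requirements,
#'   capital share, effectiveness at full coverage, and cause group.
#' @export
generate_catalog <- function(n_interventions = 188L, seed = 20301L,
                             m_counts = NULL) {
  if (length(n_interventions) != 1 || n_interventions < 1) {
    stop("n_interventions must be a positive count", call. = FALSE)
  }
  if (is.null(m_counts)) {
    m_counts <- cummax(round(n_interventions * c(143, 152, 160) / 188))
  }
  m_counts <- as.integer(m_counts)
  if (length(m_counts) != 3 || any(is.na(m_counts)) || any(diff(m_counts) < 0) ||
      m_counts[3] > n_interventions || m_counts[1] < 0) {
    stop("measure counts must be non-decreasing and within the catalog size",
         call. = FALSE)
  }
  n <- as.integer(n_interventions)

  withr_seed(seed, {
    id <- sprintf("I%03d", seq_len(n))
    block <- rep("none", n)
    block[seq_len(m_counts[1])] <- "m1"
    if (m_counts[2] > m_counts[1]) block[(m_counts[1] + 1):m_counts[2]] <- "m2"
    if (m_counts[3] > m_counts[2]) block[(m_counts[2] + 1):m_counts[3]] <- "m3"

    platform <- character(n)
    cause <- character(n)
    name <- sprintf("Intervention %03d", seq_len(n))

    causes_clinical <- c("maternal", "neonatal", "post_neonatal", "stillbirth",
                         "ncd", "cancer", "tb", "hiv", "ntd", "other")
    w_clinical <- c(0.08, 0.08, 0.17, 0.04, 0.21, 0.07, 0.08, 0.10, 0.08, 0.09)
    for (b in c("m1", "m2", "m3", "none")) {
      idx <- which(block == b)
      if (!length(idx)) next
      platform[idx] <- switch(b,
        m1 = sample(c("policy_population", "outreach", "first_level_clinical",
                      "first_level_and_above"), length(idx), replace = TRUE,
                    prob = c(0.15, 0.2, 0.45, 0.2)),
        m2 = sample(c("first_level_clinical", "first_level_and_above"),
                    length(idx), replace = TRUE, prob = c(0.6, 0.4)),
        m3 = rep("cross_sectoral", length(idx)),
        none = rep("first_level_and_above", length(idx)))
      cause[idx] <- switch(b,
        m1 = sample(causes_clinical, length(idx), replace = TRUE,
                    prob = w_clinical),
        m2 = sample(c("maternal", "neonatal", "stillbirth"), length(idx),
                    replace = TRUE, prob = c(0.35, 0.45, 0.20)),
        m3 = sample(c("post_neonatal", "other"), length(idx), replace = TRUE,
                    prob = c(0.7, 0.3)),
        none = sample(c("ncd", "cancer", "other"), length(idx), replace = TRUE,
                      prob = c(0.4, 0.3, 0.3)))
    }

    out <- tibble::tibble(
      intervention_id = id,
      name = name,
      platform = platform,
      m1 = block == "m1",
      m2 = block %in% c("m1", "m2"),
      m3 = block %in% c("m1", "m2", "m3"),
      target_pop_fraction = stats::rbeta(n, 1.2, 8),
      in_need_fraction = stats::rbeta(n, 1.5, 8),
      units_per_case = stats::rpois(n, 2) + 1,
      commodity_price = stats::rlnorm(n, log(1.2), 0.8),
      visits_per_case = stats::rpois(n, 1.8),
      minutes_per_visit = stats::runif(n, 10, 40),
      capital_share = stats::runif(n, 0, 0.15),
      effectiveness = stats::rbeta(n, 1.5, 20),
      cause_group = cause
    )
    # policy/population platforms act without patient contact
    pol <- out$platform == "policy_population"
    out$visits_per_case[pol] <- 0
    out$units_per_case[pol] <- 0

    # embed the named example interventions where the block sizes allow
    nm <- named_interventions()
    for (b in c("m1", "m2", "m3")) {
      rows <- which(block == b)
      ex <- nm[nm$block == b, ]
      k <- min(length(rows), nrow(ex))
      if (k > 0) {
        sl <- rows[seq_len(k)]
        out$name[sl] <- ex$name[seq_len(k)]
        out$platform[sl] <- ex$platform[seq_len(k)]
        out$cause_group[sl] <- ex$cause_group[seq_len(k)]
        out$visits_per_case[sl] <-
          ifelse(ex$platform[seq_len(k)] == "policy_population", 0,
                 pmax(1, out$visits_per_case[sl]))
      }
    }
    out
  })
}

#' Subset a catalog to the interventions in a measure
#'
#' @param catalog Catalog tibble from [generate_catalog()] (or user table
#'   with the same columns).
#' @param measure A [measure_spec()] object or a measure id string.
#' @return The catalog rows flagged for the measure. By nesting the result
#'   for `m1` is contained in `m2`, which is contained in `m3`.
#' @export
interventions_in_measure <- function(catalog, measure) {
  id <- if (inherits(measure, "measure_spec")) measure$measure_id else measure
  if (!is.character(id) || !id %in% c("m1", "m2", "m3")) {
    stop("unknown measure id: ", paste(id, collapse = ","), call. = FALSE)
  }
  viol <- validate_catalog(catalog)
  nest_viol <- viol[viol$field == "nesting", , drop = FALSE]
  if (nrow(nest_viol)) {
    stop("catalog violates measure nesting for ",
         paste(utils::head(nest_viol$intervention_id, 3), collapse = ", "),
         call. = FALSE)
  }
  catalog[catalog[[id]], , drop = FALSE]
}

#' Validate a catalog against the intervention invariants
#'
#' Reports (rather than raises) violations: fractions outside `[0, 1]`,
#' negative prices/units/visits/minutes, and broken measure nesting
#' (membership in a narrower measure without the wider ones).
#'
#' @param catalog Catalog tibble.
#' @return A tibble of violations with columns `intervention_id`, `field`,
#'   `message`; zero rows when the catalog is well formed.
#' @export
validate_catalog <- function(catalog) {
  v <- list()
  add <- function(idx, field, msg) {
    if (any(idx)) {
      v[[length(v) + 1]] <<- tibble::tibble(
        intervention_id = catalog$intervention_id[idx],
        field = field, message = msg)
    }
  }
  frac_fields <- c("target_pop_fraction", "in_need_fraction", "capital_share",
                   "effectiveness")
  for (f in frac_fields) {
    if (f %in% names(catalog)) {
      add(catalog[[f]] < 0 | catalog[[f]] > 1, f, "fraction outside [0, 1]")
    }
  }
  nonneg <- c("units_per_case", "commodity_price", "visits_per_case",
              "minutes_per_visit")
  for (f in nonneg) {
    if (f %in% names(catalog)) add(catalog[[f]] < 0, f, "negative value")
  }
  add(catalog$m1 & !(catalog$m2 & catalog$m3), "nesting",
      "flagged m1 but not m2/m3")
  add(catalog$m2 & !catalog$m3, "nesting", "flagged m2 but not m3")
  if (length(v)) dplyr::bind_rows(v)
  else tibble::tibble(intervention_id = character(), field = character(),
                      message = character())
}
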