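# Abridged age structure and cause-of-death scaffolding shared by the
# generator, the costing engine and the impact model.

#' Model calendar years
#'
#' The projection runs on calendar years 2015-2030 with incremental outputs
#' reported for the investment horizon 2020-2030.
#'
#' @return Integer vector of years.
#' @export
phc_years <- function() 2015:2030

#' Investment horizon years (incremental outputs)
#' @return Integer vector 2020:2030.
#' @export
phc_horizon <- function() 2020:2030

#' Abridged age groups
#'
#' Standard abridged layout: infancy (0), early childhood (1-4), then
#' five-year groups up to the open-ended 85+ interval.
#'
#' @return A tibble with columns `age_group` (ordered labels), `age_start`
#'   and `n` (interval width in years, `Inf` for the open interval).
#' @export
phc_age_groups <- function() {
  start <- c(0L, 1L, seq(5L, 85L, by = 5L))
  n <- c(1, 4, rep(5, 16), Inf)
  lab <- c("0", "1-4",
           paste(seq(5, 80, 5), seq(9, 84, 5), sep = "-"),
           "85+")
  tibble::tibble(age_group = lab, age_start = start, n = n)
}

#' Default separation factors (ax)
#'
#' Average person-years lived in an interval by those dying in it: 0.3 years
#' for the infant interval (deaths concentrate early in infancy), half the
#' interval width elsewhere. The open interval's ax is unused (its
#' person-years come from lx/mx).
#'
#' @param n Interval widths as returned by [phc_age_groups()].
#' @return Numeric vector of ax values.
#' @export
phc_default_ax <- function(n = phc_age_groups()$n) {
  ax <- 0.5 * n
  ax[1] <- 0.3
  ax[length(ax)] <- NA_real_
  ax
}

#' Cause groups tracked by the impact model
#' @return Character vector of cause-group labels.
#' @export
phc_cause_groups <- function() {
  c("maternal", "neonatal", "post_neonatal", "stillbirth",
    "ncd", "cancer", "tb", "hiv", "ntd", "other")
}

# Proportional allocation of all-cause mortality across cause groups by age
# band and sex. Rows sum to 1; stillbirths are carried separately (they are
# not deaths of the living population and never enter the life table).
cause_allocation <- function(age_start, sex) {
  stopifnot(sex %in% c("female", "male"))
  alloc <- c(maternal = 0, neonatal = 0, post_neonatal = 0, ncd = 0,
             cancer = 0, tb = 0, hiv = 0, ntd = 0, other = 0)
  if (age_start < 1) {
    alloc[c("neonatal", "post_neonatal", "hiv", "other")] <-
      c(0.55, 0.33, 0.02, 0.10)
  } else if (age_start < 5) {
    alloc[c("post_neonatal", "ntd", "hiv", "other")] <-
      c(0.75, 0.05, 0.03, 0.17)
  } else if (age_start < 15) {
    alloc[c("other", "ntd", "tb", "hiv", "ncd")] <-
      c(0.55, 0.15, 0.10, 0.10, 0.10)
  } else if (age_start < 50) {
    if (sex == "female") {
      alloc[c("maternal", "tb", "hiv", "ncd", "cancer", "ntd", "other")] <-
        c(0.12, 0.15, 0.15, 0.22, 0.08, 0.04, 0.24)
    } else {
      alloc[c("tb", "hiv", "ncd", "cancer", "ntd", "other")] <-
        c(0.18, 0.15, 0.25, 0.07, 0.05, 0.30)
    }
  } else if (age_start < 70) {
    alloc[c("ncd", "cancer", "tb", "hiv", "ntd", "other")] <-
      c(0.45, 0.18, 0.07, 0.04, 0.02, 0.24)
  } else {
    alloc[c("ncd", "cancer", "tb", "other")] <- c(0.55, 0.15, 0.03, 0.27)
  }
  alloc
}
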