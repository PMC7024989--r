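# Abridged period life table: mx -> qx -> lx -> Lx -> Tx -> ex.

#' Build an abridged period life table
#'
#' Converts central death rates into a full abridged life table using the
#' standard recursions: `qx = n*mx / (1 + (n - ax)*mx)` (capped at 1), a
#' radix of 100 000, `Lx = n*lx - (n - ax)*dx`, and for the open-ended last
#' interval `qx = 1` and `Lx = lx/mx`.
#'
#' @param mx Central death rates (deaths per person-year) by age group; the
#'   last element is the open-ended interval.
#' @param n Interval widths in years; last element `Inf`. Defaults to the
#'   abridged layout of [phc_age_groups()] when `mx` has 19 elements.
#' @param ax Average person-years lived in the interval by those dying in it;
#'   defaults to [phc_default_ax()] conventions (0.3 for the infant interval,
#'   `n/2` elsewhere).
#' @param radix Survivors at age 0 (default 100 000).
#'
#' @return A tibble with columns `age_start`, `n`, `mx`, `ax`, `qx`, `lx`,
#'   `dx`, `Lx`, `Tx`, `ex`.
#' @examples
#' lt <- build_life_table(rep(0.02, 19))
#' lt$ex[1] # close to 1/0.02 at constant hazard
#' @export
build_life_table <- function(mx, n = NULL, ax = NULL, radix = 1e5) {
  if (any(!is.finite(mx)) || any(mx < 0)) {
    stop("mx must be non-negative and finite", call. = FALSE)
  }
  k <- length(mx)
  if (k < 2) stop("need at least two age intervals", call. = FALSE)
  if (is.null(n)) {
    if (k == 19L) n <- phc_age_groups()$n
    else stop("supply interval widths `n` for non-default age layouts",
              call. = FALSE)
  }
  stopifnot(length(n) == k)
  if (!is.infinite(n[k])) stop("last interval must be open-ended (n = Inf)",
                               call. = FALSE)
  if (is.null(ax)) {
    ax <- 0.5 * n
    ax[1] <- min(0.3, 0.5 * n[1])
    ax[k] <- NA_real_
  }
  stopifnot(length(ax) == k)

  qx <- n * mx / (1 + (n - ax) * mx)
  qx <- pmin(qx, 1)
  qx[mx == 0] <- 0
  qx[k] <- 1

  lx <- numeric(k)
  lx[1] <- radix
  for (i in seq_len(k - 1)) lx[i + 1] <- lx[i] * (1 - qx[i])
  dx <- c(-diff(lx), lx[k])

  Lx <- numeric(k)
  i <- seq_len(k - 1)
  Lx[i] <- n[i] * lx[i + 1] + ax[i] * dx[i]
  Lx[k] <- if (mx[k] > 0) lx[k] / mx[k] else 0

  Tx <- rev(cumsum(rev(Lx)))
  ex <- ifelse(lx > 0, Tx / lx, 0)

  age_start <- cumsum(c(0, n[-k]))
  tibble::tibble(age_start = age_start, n = n, mx = mx, ax = ax,
                 qx = qx, lx = lx, dx = dx, Lx = Lx, Tx = Tx, ex = ex)
}

#' Life expectancy at birth from a life table
#' @param lt A life table from [build_life_table()].
#' @return e0 in years.
#' @export
life_expectancy <- function(lt) lt$ex[1]
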