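# Trapezoidal response shared by the temperature and moisture indices:
# 0 up to x0, linear rise to 1 at x1, plateau to x2, linear fall to 0 at
# x3. Thresholds are closed at zero (f(x0) = f(x3) = 0, the limits of
# the linear segments); degenerate zero-width segments follow the same
# limits.
trapezoid <- function(x, x0, x1, x2, x3) {
  y <- numeric(length(x))
  rise <- x > x0 & x < x1
  y[rise] <- (x[rise] - x0) / (x1 - x0)
  y[x >= x1 & x <= x2] <- 1
  fall <- x > x2 & x < x3
  y[fall] <- (x3 - x[fall]) / (x3 - x2)
  y
}

#' Weekly temperature index
#'
#' Piecewise-linear trapezoid over the developmental thresholds
#' `(DV0, DV1, DV2, DV3)`: zero at or below `DV0`, optimal (1) on
#' `[DV1, DV2]`, zero at or above `DV3`. Computed from the weekly mean
#' temperature.
#'
#' @param tavg weekly mean temperature(s), deg C (vectorised).
#' @param p a [climex_params()] object.
#' @return Index value(s) in `[0, 1]`.
#' @export
#' @examples
#' temperature_index(c(6.5, 12.25, 20, 40), preset_params("current"))
temperature_index <- function(tavg, p) {
  trapezoid(tavg, p$DV0, p$DV1, p$DV2, p$DV3)
}

#' Weekly moisture index
#'
#' Trapezoid over the soil-moisture thresholds `(SM0, SM1, SM2, SM3)`
#' (dimensionless bucket units, 1 = field capacity).
#'
#' @param sm weekly soil moisture value(s), dimensionless.
#' @inheritParams temperature_index
#' @return Index value(s) in `[0, 1]`.
#' @export
moisture_index <- function(sm, p) {
  trapezoid(sm, p$SM0, p$SM1, p$SM2, p$SM3)
}

#' Weekly growth index
#'
#' The product of the temperature and moisture indices: growth requires
#' both to be favourable in the same week.
#'
#' @param ti,mi weekly indices in `[0, 1]` (vectorised).
#' @return `ti * mi`.
#' @export
weekly_growth_index <- function(ti, mi) {
  stopifnot(all(ti >= 0 & ti <= 1), all(mi >= 0 & mi <= 1))
  ti * mi
}

#' Annual growth index
#'
#' `GI_A = 100 * mean(gi)` over the 52 weeks, a percentage in
#' `[0, 100]` summarising annual growth potential.
#'
#' @param gi 52 weekly growth-index values in `[0, 1]`.
#' @return Percentage in `[0, 100]`.
#' @export
annual_growth_index <- function(gi) {
  stopifnot(length(gi) == 52, all(gi >= 0 & gi <= 1))
  100 * mean(gi)
}

#' Annual degree-day accumulation
#'
#' `sum over weeks of 7 * max(0, tavg_w - threshold)` deg C-days. Used
#' both for the generation gate (threshold `DV0`, compared with `PDD`)
#' and, per week, for the cold-stress mechanism (threshold `DVCS`).
#'
#' @param tavg 52 weekly mean temperatures, deg C.
#' @param threshold base temperature, deg C.
#' @return Annual degree-days (deg C-days) above the threshold.
#' @export
#' @examples
#' degree_days(rep(8.5, 52), 6.5)  # 52 * 7 * 2 = 728
degree_days <- function(tavg, threshold) {
  stopifnot(length(tavg) == 52)
  sum(DAYS_PER_WEEK * pmax(0, tavg - threshold))
}

# weekly degree-days above a threshold (deg C-days / week)
weekly_degree_days <- function(tavg, threshold) {
  DAYS_PER_WEEK * pmax(0, tavg - threshold)
}
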