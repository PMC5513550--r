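# Consecutive-week counts: n_w = number of consecutive weeks ending at
# week w with positive exceedance, wrapping across the Dec->Jan boundary
# so southern-hemisphere summers are not split. When the condition holds
# in all 52 weeks the wrap is ambiguous; the count then simply runs
# n_w = w from the start of the year.
consecutive_weeks <- function(active) {
  n <- length(active)
  if (all(active)) return(seq_len(n))
  run <- integer(2 * n)
  a2 <- c(active, active)
  for (i in seq_along(a2)) {
    run[i] <- if (a2[i]) (if (i == 1) 1L else run[i - 1] + 1L) else 0L
  }
  run[(n + 1):(2 * n)]
}

#' Annual stress accumulation
#'
#' Converts 52 weekly exceedance magnitudes into an annual stress index
#' in `[0, 100]`. Stress builds faster the longer the hostile condition
#' persists: with `n_w` the number of consecutive stressed weeks ending
#' at week `w` (wrapping across the year boundary), the annual index is
#' `100 * min(1, sum_w |rate| * exceedance_w * n_w)`.
#'
#' @param exceedance 52 non-negative weekly exceedance magnitudes (zero
#'   where the stress condition is not met).
#' @param rate weekly accumulation rate (sign ignored; published tables
#'   store decline rates as negative numbers).
#' @return Annual stress index in `[0, 100]`.
#' @export
stress_accumulate <- function(exceedance, rate) {
  stopifnot(length(exceedance) == 52, all(exceedance >= 0))
  n_w <- consecutive_weeks(exceedance > 0)
  100 * min(1, sum(abs(rate) * exceedance * n_w))
}

#' Annual stress indices
#'
#' Each mechanism turns the weekly series into exceedance magnitudes and
#' feeds [stress_accumulate()]. Thresholds are strict: no stress accrues
#' in a week sitting exactly on its threshold, so the published threshold
#' values are exactly the zero-stress suprema.
#'
#' * Cold stress: shortfall of weekly degree-days above `DVCS` below the
#'   `DTCS` threshold, rate `|DHCS|`.
#' * Heat stress: weekly mean temperature above `TTHS`, rate `THHS`.
#' * Dry stress: soil moisture below `SMDS`, rate `|HDS|`.
#' * Wet stress: soil moisture above `SMWS`, rate `HWS`; a zero rate
#'   disables the mechanism (returns 0 for any input).
#' * Hot-wet stress: binary joint condition — week counts as stressed
#'   (exceedance 1) iff `tavg > TTHW` and `sm > MTHW`; rate `PHW`; zero
#'   rate disables.
#'
#' @param dd_cs 52 weekly degree-days above `DVCS` (deg C-days/week).
#' @param tavg 52 weekly mean temperatures, deg C.
#' @param sm 52 weekly soil-moisture values, dimensionless.
#' @param p a [climex_params()] object.
#' @return Annual stress index in `[0, 100]`.
#' @name stress-indices
NULL

#' @rdname stress-indices
#' @export
cold_stress <- function(dd_cs, p) {
  stopifnot(length(dd_cs) == 52, all(dd_cs >= 0))
  stress_accumulate(pmax(0, p$DTCS - dd_cs), p$DHCS)
}

#' @rdname stress-indices
#' @export
heat_stress <- function(tavg, p) {
  stopifnot(length(tavg) == 52)
  stress_accumulate(pmax(0, tavg - p$TTHS), p$THHS)
}

#' @rdname stress-indices
#' @export
dry_stress <- function(sm, p) {
  stopifnot(length(sm) == 52, all(sm >= 0))
  stress_accumulate(pmax(0, p$SMDS - sm), p$HDS)
}

#' @rdname stress-indices
#' @export
wet_stress <- function(sm, p) {
  stopifnot(length(sm) == 52, all(sm >= 0))
  if (p$HWS == 0) return(0)
  stress_accumulate(pmax(0, sm - p$SMWS), p$HWS)
}

#' @rdname stress-indices
#' @export
hot_wet_stress <- function(tavg, sm, p) {
  stopifnot(length(tavg) == 52, length(sm) == 52)
  if (p$PHW == 0) return(0)
  stress_accumulate(as.numeric(tavg > p$TTHW & sm > p$MTHW), p$PHW)
}

#' Bundle annual stresses and their combination factor
#'
#' The five parameterised mechanisms are combined multiplicatively:
#' `combined_factor = prod(1 - s/100)` in `[0, 1]`. The four interaction
#' stresses without published parameters (cold-dry, cold-wet, hot-dry and
#' a second-order hot-wet form) are structurally present but permanently
#' zero.
#'
#' @param cold,heat,dry,wet,hot_wet annual stress indices in `[0, 100]`.
#' @return A `stress_result` list with the five stresses, the inactive
#'   interaction stresses (all zero) and `combined_factor`.
#' @export
stress_result <- function(cold = 0, heat = 0, dry = 0, wet = 0, hot_wet = 0) {
  s <- c(cold = cold, heat = heat, dry = dry, wet = wet, hot_wet = hot_wet)
  if (any(s < 0 | s > 100)) stop("stress indices must lie in [0,100]",
                                 call. = FALSE)
  structure(list(cold = cold, heat = heat, dry = dry, wet = wet,
                 hot_wet = hot_wet,
                 cold_dry = 0, cold_wet = 0, hot_dry = 0,
                 combined_factor = prod(1 - s / 100)),
            class = "stress_result")
}

#' @export
print.stress_result <- function(x, ...) {
  cat("<stress_result>\n")
  cat(sprintf("  cold %.2f  heat %.2f  dry %.2f  wet %.2f  hot-wet %.2f\n",
              x$cold, x$heat, x$dry, x$wet, x$hot_wet))
  cat(sprintf("  combined survival factor: %.4f\n", x$combined_factor))
  invisible(x)
}

#' Combined stress survival factor
#'
#' @param stresses a [stress_result()] object.
#' @return `prod(1 - s/100)` over the five stresses, in `[0, 1]`.
#' @export
combine_stresses <- function(stresses) {
  stopifnot(inherits(stresses, "stress_result"))
  stresses$combined_factor
}

# all five stresses from the weekly series
annual_stresses <- function(tavg, sm, p) {
  dd_cs <- weekly_degree_days(tavg, p$DVCS)
  stress_result(
    cold = cold_stress(dd_cs, p),
    heat = heat_stress(tavg, p),
    dry = dry_stress(sm, p),
    wet = wet_stress(sm, p),
    hot_wet = hot_wet_stress(tavg, sm, p)
  )
}
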