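#' Irrigation scenario
#'
#' The published scenario is summer top-up irrigation at 2.5 mm/day:
#' during the local summer half-year, weekly rainfall is raised to at
#' least `7 * rate` mm/week (never added on top of wetter weeks, and
#' never reduced).
#'
#' @param rate irrigation rate in mm/day (default 2.5).
#' @param season `"summer"` or `"none"`.
#' @return An `irrigation_scenario` object.
#' @export
irrigation_scenario <- function(rate = 2.5, season = c("summer", "none")) {
  season <- match.arg(season)
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate < 0) {
    stop("irrigation rate must be a single non-negative number", call. = FALSE)
  }
  structure(list(rate = rate, season = season, mode = "top_up"),
            class = "irrigation_scenario")
}

# Local summer weeks: northern hemisphere weeks 18-44 (approx May-Oct),
# southern weeks 1-17 and 45-52 (approx Nov-Apr). |lat| < 1 deg is
# treated as northern.
summer_weeks <- function(lat) {
  if (lat <= -1) c(1:17, 45:52) else 18:44
}

#' Apply top-up irrigation to weekly rainfall
#'
#' @param precip numeric vector of 52 weekly rainfall totals (mm/week).
#' @param lat latitude in degrees (south negative); selects the summer
#'   half-year.
#' @param scen an [irrigation_scenario()], or `NULL` for no irrigation.
#' @return 52 weekly effective-rainfall totals; always `>= precip`.
#' @export
#' @examples
#' p <- rep(2, 52)
#' apply_irrigation(p, lat = -41, irrigation_scenario(2.5))[1]  # 17.5
apply_irrigation <- function(precip, lat, scen = irrigation_scenario()) {
  stopifnot(length(precip) == 52, all(is.finite(precip)))
  if (is.null(scen) || scen$season == "none" || scen$rate == 0) return(precip)
  stopifnot(inherits(scen, "irrigation_scenario"))
  out <- precip
  sw <- summer_weeks(lat)
  out[sw] <- pmax(out[sw], DAYS_PER_WEEK * scen$rate)
  out
}

#' Weekly potential evapotranspiration
#'
#' An explicit temperature/humidity demand term standing in for the
#' closed-source hydrology of commercial niche-modelling software:
#' `Ep = 7 * k_et * max(0, tavg) * (1 - rh)` mm/week. It is zero at or
#' below freezing and in saturated air, and decreasing in humidity.
#' `k_et` (mm/day per deg C) is exposed so the sensitivity of results to
#' this stand-in can be probed.
#'
#' @param tavg weekly mean temperature(s), deg C.
#' @param rh weekly relative humidity (fraction in `[0,1]`).
#' @param k_et demand coefficient, mm/day per deg C (default 0.6).
#' @return Potential evapotranspiration, mm/week (vectorised).
#' @export
#' @examples
#' potential_et(20, 0.5)   # 42
potential_et <- function(tavg, rh, k_et = 0.6) {
  if (any(rh < 0 | rh > 1)) stop("rh must lie in [0,1]", call. = FALSE)
  DAYS_PER_WEEK * k_et * pmax(0, tavg) * (1 - rh)
}

# One pass over the 52-week year. Actual evapotranspiration is
# soil-limited: Ea = Ep * min(1, sm_prev). Moisture above field capacity
# is retained up to sm_cap (so supersaturation thresholds like SM3 = 2.5
# are reachable); the excess leaves as runoff.
bucket_pass <- function(sm0, precip, et_pot, capacity, sm_cap) {
  n <- length(precip)
  sm <- numeric(n)
  et <- numeric(n)
  prev <- sm0
  for (w in seq_len(n)) {
    et[w] <- et_pot[w] * min(1, prev)
    prev <- min(max(prev + (precip[w] - et[w]) / capacity, 0), sm_cap)
    sm[w] <- prev
  }
  list(sm = sm, et = et)
}

#' Run the single-bucket soil-moisture model to its annual cycle
#'
#' A 100 mm single-bucket model on the weekly timestep: soil moisture is
#' expressed as a fraction of the bucket (0 = oven dry, 1 = field
#' capacity). The update is
#' `sm_w = clamp(sm_{w-1} + (P_w - Ea_w)/capacity, 0, sm_cap)` with
#' soil-limited actual evapotranspiration `Ea_w = Ep_w * min(1, sm_{w-1})`.
#' The year is iterated with the final week's moisture carried over until
#' the annual cycle converges (`max |delta sm| < tol`), so the reported
#' series is the climate's equilibrium seasonal cycle, independent of the
#' initial state.
#'
#' @param precip effective rainfall, mm/week (length 52).
#' @param et_pot potential evapotranspiration, mm/week (length 52).
#' @param capacity bucket size in mm (default 100).
#' @param sm_init initial moisture for the spin-up (default 0.5).
#' @param sm_cap upper bound on the dimensionless moisture (default 5):
#'   supersaturation allowance above field capacity before runoff.
#' @param tol spin-up convergence tolerance (default 1e-6).
#' @param max_cycles spin-up iteration cap (default 100).
#' @return A `soil_moisture_series` list: `sm`, `effective_precip`, `et`
#'   (each length 52), `cycles` used.
#' @export
run_bucket <- function(precip, et_pot, capacity = 100, sm_init = 0.5,
                       sm_cap = 5, tol = 1e-6, max_cycles = 100) {
  stopifnot(length(precip) == 52, length(et_pot) == 52, capacity > 0,
            all(precip >= 0), all(et_pot >= 0), sm_init >= 0)
  prev <- rep(NA_real_, 52)
  sm0 <- min(sm_init, sm_cap)
  for (cycle in seq_len(max_cycles)) {
    res <- bucket_pass(sm0, precip, et_pot, capacity, sm_cap)
    if (!anyNA(prev) && max(abs(res$sm - prev)) < tol) {
      return(structure(list(sm = res$sm, effective_precip = precip,
                            et = res$et, cycles = cycle),
                       class = "soil_moisture_series"))
    }
    sm0 <- res$sm[52]
    # Near-balanced budgets drift linearly while the whole year sits
    # above field capacity (Ea is then moisture-independent). Once the
    # cycle shape has converged up to a uniform drift, jump the carry-
    # over state to the edge of that linear regime instead of crawling.
    if (!anyNA(prev)) {
      d <- res$sm[52] - prev[52]
      if (abs(d) >= tol && max(abs(res$sm - prev - d)) < tol) {
        k <- if (d > 0) (sm_cap - max(res$sm)) / d else (min(res$sm) - 1) / (-d)
        sm0 <- min(max(res$sm[52] + d * max(0, k), 0), sm_cap)
      }
    }
    prev <- res$sm
  }
  stop("soil-moisture spin-up failed to converge within ", max_cycles,
       " cycles", call. = FALSE)
}
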