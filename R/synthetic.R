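# Synthetic monthly-normal generator. Five archetypes span the climates
# the model contrasts: cold xeric steppe (southern hemisphere),
# Mediterranean winter-rain, hot-humid tropics, cold alpine, and a
# constant stress-free optimum. Monthly normals follow a sinusoidal
# annual cycle:
#   tavg_m = mean + amp * cos(2*pi*(m - peak)/12)
#   precip_m = (annual/12) * (1 + seas * cos(2*pi*(m - wet_peak)/12))
# with a fixed diurnal range and constant 09h/15h humidity levels.
# All randomness is a small jitter on the base constants; contracts are
# asserted after generation and the draw is retried (continuing the
# seeded stream) up to a bounded number of attempts.

.PROFILES <- c("patagonia_xeric", "mediterranean", "tropical_hot_wet",
               "alpine_cold", "optimal_constant")

#' Available synthetic climate profiles
#' @return Character vector of profile names.
#' @export
climate_profiles <- function() .PROFILES

# month of warmest tavg / wettest month given hemisphere
.peak_month <- function(lat, winter_wet) {
  warm <- if (lat < 0) 1 else 7     # mid-Jan / mid-Jul
  wet <- if (winter_wet) ((warm + 5) %% 12) + 1 else warm
  list(warm = warm, wet = wet)
}

.seasonal <- function(mean, amp, peak) {
  mean + amp * cos(2 * pi * ((1:12) - peak) / 12)
}

# one jittered draw of a profile's monthly normals
.draw_profile <- function(profile) {
  u <- function(lo, hi) stats::runif(1, lo, hi)
  switch(profile,
    patagonia_xeric = {
      lat <- u(-44, -40)
      tmean <- 11.75 + u(-0.25, 0.25)
      tamp <- 7.25 + u(-0.25, 0.25)
      pk <- .peak_month(lat, winter_wet = TRUE)
      tavg <- .seasonal(tmean, tamp, pk$warm)
      precip <- (u(55, 70) / 12) *
        (1 + 0.35 * cos(2 * pi * ((1:12) - pk$wet) / 12))
      # steppe air is driest in late spring (westerlies), moistest in
      # autumn: seasonal RH cycle peaking in April (austral autumn)
      rh_cycle <- 0.10 * cos(2 * pi * ((1:12) - 4) / 12)
      list(lat = lat, lon = u(-72, -68), tavg = tavg, dtr = 10,
           precip = precip, rh09 = 0.55 + rh_cycle, rh15 = 0.35 + rh_cycle)
    },
    mediterranean = {
      lat <- u(35, 39)
      pk <- .peak_month(lat, winter_wet = TRUE)
      tavg <- .seasonal(16 + u(-0.5, 0.5), 7 + u(-0.3, 0.3), pk$warm)
      precip <- (u(480, 620) / 12) *
        (1 + 0.6 * cos(2 * pi * ((1:12) - pk$wet) / 12))
      list(lat = lat, lon = u(-6, 2), tavg = tavg, dtr = 9,
           precip = precip, rh09 = 0.70, rh15 = 0.50)
    },
    tropical_hot_wet = {
      lat <- u(1, 6)
      pk <- .peak_month(lat, winter_wet = FALSE)
      tavg <- .seasonal(26.5 + u(-0.5, 0.5), 1.2 + u(-0.2, 0.2), pk$warm)
      precip <- (u(2000, 2600) / 12) *
        (1 + 0.3 * cos(2 * pi * ((1:12) - pk$wet) / 12))
      list(lat = lat, lon = u(100, 110), tavg = tavg, dtr = 8,
           precip = precip, rh09 = 0.88, rh15 = 0.72)
    },
    alpine_cold = {
      lat <- u(-32, -28)
      pk <- .peak_month(lat, winter_wet = FALSE)
      tavg <- .seasonal(0 + u(-0.5, 0.5), 4 + u(-0.5, 0.5), pk$warm)
      precip <- rep(u(300, 500) / 12, 12)
      list(lat = lat, lon = u(-71, -69), tavg = tavg, dtr = 8,
           precip = precip, rh09 = 0.70, rh15 = 0.50)
    },
    optimal_constant = {
      lat <- u(-36, -32)
      rh <- 0.5
      target_sm <- u(0.88, 1.02)
      ep_week <- DAYS_PER_WEEK * 0.6 * 22 * (1 - rh)   # default k_et
      precip <- rep(target_sm * ep_week * 52 / 12, 12)
      list(lat = lat, lon = u(18, 22), tavg = rep(22, 12), dtr = 10,
           precip = precip, rh09 = rh, rh15 = rh)
    },
    stop("unknown profile '", profile, "'; valid profiles: ",
         paste(.PROFILES, collapse = ", "), call. = FALSE)
  )
}

# Contract checks, run on the generated site through the default
# pipeline (irrigation-aware preset, default hydrology). Returns NULL
# when satisfied, else the name of the violated contract.
.check_profile <- function(profile, site) {
  tavg <- (site$tmin + site$tmax) / 2
  summer <- if (site$lat < 0) c(12, 1, 2) else 6:8
  winter <- if (site$lat < 0) 6:8 else c(12, 1, 2)
  rh <- mean(c(site$rh09, site$rh15))
  p <- preset_params("current")
  switch(profile,
    patagonia_xeric = {
      if (site$lat >= 0) return("southern hemisphere")
      if (sum(site$precip) >= 250) return("annual precip < 250 mm")
      if (sum(site$precip[winter]) <= sum(site$precip[summer])) {
        return("precip concentrated in winter")
      }
      st <- mean(tavg[summer])
      if (st < 12 || st > 22) return("summer tavg in [12,22]")
      if (mean(tavg[winter]) >= 5) return("winter tavg < 5")
      nat <- run_location(site, p, NULL)
      grow <- nat$weekly$ti > 0
      if (any(nat$weekly$sm[grow] >= p$SM0)) {
        return("growing-season soil moisture below SM0")
      }
      NULL
    },
    mediterranean = {
      if (sum(site$precip[winter]) <= sum(site$precip[summer])) {
        return("winter-wet, summer-dry")
      }
      if (min(tavg) < 8 || max(tavg) > 24) return("tavg annual cycle 8-24")
      NULL
    },
    tropical_hot_wet = {
      if (min(tavg) <= 24) return("all-month tavg > 24")
      if (sum(site$precip) <= 1800) return("annual precip > 1800 mm")
      if (rh <= 0.7) return("RH > 0.7")
      NULL
    },
    alpine_cold = if (max(tavg) >= 6) "all-month tavg < 6" else NULL,
    optimal_constant = {
      if (any(abs(tavg - 22) > 1e-9)) return("tavg constant at 22")
      nat <- run_location(site, p, NULL)
      if (any(nat$weekly$sm < 0.8 | nat$weekly$sm > 1.2)) {
        return("spun-up soil moisture in [0.8, 1.2]")
      }
      NULL
    }
  )
}

#' Generate a synthetic site of monthly climate normals
#'
#' Deterministic for a given `(profile, seed)`. Each profile carries a
#' contract (hemisphere, temperature envelope, rainfall totals and
#' seasonality, and for the steppe and optimum profiles the behaviour of
#' the spun-up soil-moisture cycle); contracts are verified after
#' generation and the jittered draw is retried, continuing the seeded
#' random stream, up to `max_tries` times.
#'
#' @param profile one of [climate_profiles()].
#' @param seed integer seed; equal seeds give identical sites.
#' @param max_tries bound on contract-violation retries (default 20).
#' @return A [location_climate()] object.
#' @export
#' @examples
#' site <- make_site("optimal_constant", seed = 1)
#' run_location(site, preset_params("current"))$ei   # 100
make_site <- function(profile, seed, max_tries = 20) {
  profile <- match.arg(profile, .PROFILES)
  stopifnot(is.numeric(seed), length(seed) == 1)
  with_local_seed(seed, {
    violated <- NULL
    for (attempt in seq_len(max_tries)) {
      d <- .draw_profile(profile)
      site <- location_climate(
        site_id = sprintf("%s_s%d", profile, as.integer(seed)),
        lat = d$lat, lon = d$lon,
        tmin = d$tavg - d$dtr / 2, tmax = d$tavg + d$dtr / 2,
        precip = d$precip,
        rh09 = rep(d$rh09, length.out = 12),
        rh15 = rep(d$rh15, length.out = 12)
      )
      violated <- .check_profile(profile, site)
      if (is.null(violated)) return(site)
    }
    stop("profile '", profile, "' violated contract \"", violated,
         "\" after ", max_tries, " attempts", call. = FALSE)
  })
}

# evaluate expr under a private RNG state, restoring the caller's
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# profile for a cell given row/col fractions (r: 0 cold -> 1 hot;
# c: 0 arid -> 1 wet)
.grid_profile <- function(r, c) {
  if (r < 0.2) return("alpine_cold")
  if (r < 0.55) return(if (c < 0.5) "patagonia_xeric" else "mediterranean")
  if (r < 0.8) return(if (c < 0.4) "mediterranean" else "optimal_constant")
  "tropical_hot_wet"
}

#' Generate a synthetic climate grid with an irrigation mask
#'
#' Cells follow a latitudinal temperature gradient (cold alpine rows
#' through steppe and Mediterranean bands to hot-humid tropics) and a
#' longitudinal aridity gradient (arid west, wet east), spanning all
#' five profiles. The irrigation mask is `TRUE` on a contiguous patch
#' inside the arid steppe sector, emulating irrigated agriculture in a
#' desert.
#'
#' @param nrow,ncol grid dimensions (each at least 1).
#' @param seed integer seed; deterministic as for [make_site()].
#' @return A `climate_grid` list: `sites` (row-major list of
#'   [location_climate()]), `mask` (logical), `nrow`, `ncol`.
#' @export
make_grid <- function(nrow, ncol, seed) {
  stopifnot(nrow >= 1, ncol >= 1)
  n <- as.integer(nrow) * as.integer(ncol)
  sites <- vector("list", n)
  mask <- logical(n)
  # contiguous irrigated patch: middle rows of the arid steppe sector
  arid_cols <- seq_len(max(1L, floor(ncol / 2)))
  steppe_rows <- which(vapply(seq_len(nrow), function(i) {
    r <- if (nrow == 1) 0.5 else (i - 1) / (nrow - 1)
    r >= 0.2 && r < 0.55
  }, logical(1)))
  patch_rows <- steppe_rows[seq_len(min(2L, length(steppe_rows)))]
  for (i in seq_len(nrow)) {
    for (j in seq_len(ncol)) {
      cell <- (i - 1L) * ncol + j
      r <- if (nrow == 1) 0.5 else (i - 1) / (nrow - 1)
      c <- if (ncol == 1) 0.5 else (j - 1) / (ncol - 1)
      prof <- .grid_profile(r, c)
      site <- make_site(prof, seed = seed + 1000L * cell)
      site$site_id <- sprintf("cell_r%02d_c%02d_%s", i, j, prof)
      # grid coordinates: south-cold to equator-hot, arid-west to wet-east
      grid_lat <- -55 + 50 * r
      if (sign(grid_lat) != sign(site$lat) && grid_lat != 0) {
        # assigned hemisphere differs from the profile's native one:
        # rotate the annual cycle by six months to keep phase physical
        rot <- function(v) v[c(7:12, 1:6)]
        for (v in c("tmin", "tmax", "precip", "rh09", "rh15")) {
          site[[v]] <- rot(site[[v]])
        }
      }
      site$lat <- grid_lat
      site$lon <- -75 + 40 * c
      sites[[cell]] <- site
      mask[cell] <- prof == "patagonia_xeric" && i %in% patch_rows &&
        j %in% arid_cols
    }
  }
  names(sites) <- vapply(sites, function(s) s$site_id, character(1))
  structure(list(sites = sites, mask = mask, nrow = as.integer(nrow),
                 ncol = as.integer(ncol)),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat("<climate_grid>", x$nrow, "x", x$ncol, "cells;",
      sum(x$mask), "irrigated\n")
  invisible(x)
}
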