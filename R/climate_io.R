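#' Monthly climate normals for one location
#'
#' Long-term monthly normals of the five driving variables: minimum and
#' maximum temperature (deg C), precipitation (mm/month) and relative
#' humidity at 09h00 and 15h00 (fraction). Latitude is signed (south
#' negative); the sign selects the local summer half-year for the
#' irrigation scenario.
#'
#' @param site_id character identifier.
#' @param lat,lon coordinates in degrees; `lat` in `[-90, 90]`.
#' @param tmin,tmax,precip,rh09,rh15 numeric vectors of length 12.
#' @return A `location_climate` object.
#' @export
location_climate <- function(site_id, lat, lon, tmin, tmax, precip, rh09, rh15) {
  x <- list(site_id = as.character(site_id), lat = as.numeric(lat),
            lon = as.numeric(lon), tmin = as.numeric(tmin),
            tmax = as.numeric(tmax), precip = as.numeric(precip),
            rh09 = as.numeric(rh09), rh15 = as.numeric(rh15))
  class(x) <- "location_climate"
  validate_location_climate(x)
  x
}

validate_location_climate <- function(x) {
  id <- x$site_id
  for (v in c("tmin", "tmax", "precip", "rh09", "rh15")) {
    if (length(x[[v]]) != 12 || anyNA(x[[v]])) {
      stop("site ", id, ": ", v, " must be 12 finite monthly values",
           call. = FALSE)
    }
  }
  if (!is.finite(x$lat) || abs(x$lat) > 90) {
    stop("site ", id, ": lat must lie in [-90, 90]", call. = FALSE)
  }
  bad <- which(x$tmin > x$tmax)
  if (length(bad) > 0) {
    stop("site ", id, ": tmin exceeds tmax in month ", bad[1], call. = FALSE)
  }
  if (any(x$precip < 0)) {
    stop("site ", id, ": negative precipitation in month ",
         which(x$precip < 0)[1], call. = FALSE)
  }
  for (v in c("rh09", "rh15")) {
    if (any(x[[v]] < 0 | x[[v]] > 1)) {
      stop("site ", id, ": ", v, " outside [0,1] in month ",
           which(x[[v]] < 0 | x[[v]] > 1)[1], call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.location_climate <- function(x, ...) {
  cat("<location_climate>", x$site_id,
      sprintf("(lat %.2f, lon %.2f)\n", x$lat, x$lon))
  cat(sprintf("  tavg %.1f..%.1f degC, annual precip %.0f mm, mean RH %.2f\n",
              min((x$tmin + x$tmax) / 2), max((x$tmin + x$tmax) / 2),
              sum(x$precip), mean(c(x$rh09, x$rh15))))
  invisible(x)
}

climate_cols <- function() {
  c("site_id", "lat", "lon",
    paste0("tmin_", 1:12), paste0("tmax_", 1:12), paste0("precip_", 1:12),
    paste0("rh09_", 1:12), paste0("rh15_", 1:12))
}

#' Read / write a climate-normals table
#'
#' The tabular layout mirrors gridded monthly-normals archives flattened
#' to one row per site or grid cell: `site_id, lat, lon` followed by
#' twelve-month blocks `tmin_1..tmin_12, tmax_1..tmax_12,
#' precip_1..precip_12, rh09_1..rh09_12, rh15_1..rh15_12` (CSV). Grid
#' exports carry extra `row`/`col` columns, preserved as attributes.
#' All row-level invariants are enforced on read; a malformed row fails
#' with its `site_id` named.
#'
#' @param path CSV file path.
#' @return `read_climate_table()` returns a list of [location_climate()]
#'   objects (named by `site_id`).
#' @export
read_climate_table <- function(path) {
  if (!file.exists(path)) stop("climate file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- climate_cols()
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("climate table missing column(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) stop("climate table has no rows", call. = FALSE)
  sites <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    location_climate(
      site_id = r$site_id, lat = r$lat, lon = r$lon,
      tmin = as.numeric(r[paste0("tmin_", 1:12)]),
      tmax = as.numeric(r[paste0("tmax_", 1:12)]),
      precip = as.numeric(r[paste0("precip_", 1:12)]),
      rh09 = as.numeric(r[paste0("rh09_", 1:12)]),
      rh15 = as.numeric(r[paste0("rh15_", 1:12)])
    )
  })
  names(sites) <- vapply(sites, function(s) s$site_id, character(1))
  sites
}

#' @param sites list of [location_climate()] objects.
#' @rdname read_climate_table
#' @export
write_climate_table <- function(sites, path) {
  if (inherits(sites, "location_climate")) sites <- list(sites)
  if (length(sites) == 0) stop("no sites to write", call. = FALSE)
  rows <- lapply(sites, function(s) {
    as.data.frame(c(
      list(site_id = s$site_id, lat = s$lat, lon = s$lon),
      stats::setNames(as.list(s$tmin), paste0("tmin_", 1:12)),
      stats::setNames(as.list(s$tmax), paste0("tmax_", 1:12)),
      stats::setNames(as.list(s$precip), paste0("precip_", 1:12)),
      stats::setNames(as.list(s$rh09), paste0("rh09_", 1:12)),
      stats::setNames(as.list(s$rh15), paste0("rh15_", 1:12))
    ))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

# Model year: 52 weeks of 7 days (364 days), week 1 starting 1 January.
# Months are treated as equal twelfths of the year; month m has its
# midpoint at day (m - 0.5) * 364/12, week w at day 7w - 3.5.
WEEKS_PER_YEAR <- 52L
DAYS_PER_WEEK <- 7

# Periodic piecewise-linear interpolation from 12 monthly values to the
# 52 weekly midpoints. Guarantees each weekly value lies between the two
# bracketing monthly values.
interp_monthly <- function(monthly) {
  month_mid <- ((1:12) - 0.5) * 364 / 12
  week_mid <- 7 * (1:52) - 3.5
  x <- c(month_mid[12] - 364, month_mid, month_mid[1] + 364)
  y <- c(monthly[12], monthly, monthly[1])
  stats::approx(x, y, xout = week_mid)$y
}

#' Expand monthly normals to a 52-week year
#'
#' Temperatures and relative humidity are interpolated piecewise-linearly
#' between month midpoints with periodic wrap (December to January);
#' weekly RH is the mean of the interpolated 09h00 and 15h00 values.
#' Precipitation is interpolated as a weekly rate and then rescaled so
#' the annual weekly sum equals the annual monthly total exactly.
#'
#' @param clim a [location_climate()] object.
#' @return A `weekly_climate` list with elements `tavg`, `tmin`, `tmax`
#'   (deg C), `precip` (mm/week), `rh` (fraction), each of length 52,
#'   plus `site_id` and `lat`.
#' @export
monthly_to_weekly <- function(clim) {
  stopifnot(inherits(clim, "location_climate"))
  tmin <- interp_monthly(clim$tmin)
  tmax <- interp_monthly(clim$tmax)
  rh <- (interp_monthly(clim$rh09) + interp_monthly(clim$rh15)) / 2
  # monthly mm/month -> mm/week rate at the monthly midpoints
  rate <- interp_monthly(clim$precip * 12 / 52)
  annual <- sum(clim$precip)
  precip <- if (annual > 0 && sum(rate) > 0) rate * annual / sum(rate) else rate
  structure(list(site_id = clim$site_id, lat = clim$lat,
                 tavg = (tmin + tmax) / 2, tmin = tmin, tmax = tmax,
                 precip = precip, rh = rh),
            class = "weekly_climate")
}
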