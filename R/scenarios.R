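#' Run the full annual pipeline for one location
#'
#' Deterministic composition of every stage: expand the monthly normals
#' to 52 weeks, apply the irrigation scenario (if any) to rainfall,
#' compute evaporative demand and spin up the soil-moisture bucket, then
#' the weekly temperature/moisture/growth indices, the annual stresses
#' and the Ecoclimatic Index with its suitability class.
#'
#' @param clim a [location_climate()] object.
#' @param p a [climex_params()] object.
#' @param scen an [irrigation_scenario()], or `NULL` for natural
#'   rainfall.
#' @param hydro list of hydrology settings: `k_et`, `capacity_mm`,
#'   `sm_cap`, `sm_init`, `spinup_tol`, `spinup_max_cycles`.
#' @return An `annual_indices` object: `gi_a`, `stresses`
#'   (a [stress_result()]), `dd_annual`, `ei`, `ei_class`, `suitable`,
#'   plus the `weekly` data frame (week, tavg, precip_effective, sm, ti,
#'   mi, gi) behind them.
#' @export
run_location <- function(clim, p, scen = NULL, hydro = hydro_defaults()) {
  stopifnot(inherits(clim, "location_climate"), inherits(p, "climex_params"))
  wk <- monthly_to_weekly(clim)
  eff <- apply_irrigation(wk$precip, clim$lat, scen)
  ep <- potential_et(wk$tavg, wk$rh, k_et = hydro$k_et)
  bucket <- run_bucket(eff, ep, capacity = hydro$capacity_mm,
                       sm_init = hydro$sm_init, sm_cap = hydro$sm_cap,
                       tol = hydro$spinup_tol,
                       max_cycles = hydro$spinup_max_cycles)
  ti <- temperature_index(wk$tavg, p)
  mi <- moisture_index(bucket$sm, p)
  gi <- weekly_growth_index(ti, mi)
  gi_a <- annual_growth_index(gi)
  dd_annual <- degree_days(wk$tavg, p$DV0)
  stresses <- annual_stresses(wk$tavg, bucket$sm, p)
  ei <- ecoclimatic_index(gi_a, stresses, dd_annual, p)
  structure(list(
    site_id = clim$site_id,
    gi_a = gi_a, stresses = stresses, dd_annual = dd_annual,
    ei = ei, ei_class = as.character(classify_ei(ei)),
    suitable = is_suitable(ei),
    weekly = data.frame(week = 1:52, tavg = wk$tavg,
                        precip_effective = eff, sm = bucket$sm,
                        ti = ti, mi = mi, gi = gi)
  ), class = "annual_indices")
}

#' @export
print.annual_indices <- function(x, ...) {
  cat("<annual_indices>", x$site_id, "\n")
  cat(sprintf("  EI %.2f (%s)  GI_A %.2f  degree-days %.0f\n",
              x$ei, x$ei_class, x$gi_a, x$dd_annual))
  s <- x$stresses
  cat(sprintf("  stresses: cold %.1f heat %.1f dry %.1f wet %.1f hot-wet %.1f\n",
              s$cold, s$heat, s$dry, s$wet, s$hot_wet))
  invisible(x)
}

#' Hydrology settings
#'
#' @param k_et evaporative-demand coefficient, mm/day per deg C.
#' @param capacity_mm bucket size, mm.
#' @param sm_cap supersaturation cap (dimensionless).
#' @param sm_init spin-up starting moisture.
#' @param spinup_tol,spinup_max_cycles spin-up convergence controls.
#' @return A named list passed to [run_location()].
#' @export
hydro_defaults <- function(k_et = 0.6, capacity_mm = 100, sm_cap = 5,
                           sm_init = 0.5, spinup_tol = 1e-6,
                           spinup_max_cycles = 100) {
  list(k_et = k_et, capacity_mm = capacity_mm, sm_cap = sm_cap,
       sm_init = sm_init, spinup_tol = spinup_tol,
       spinup_max_cycles = spinup_max_cycles)
}

#' Gridded risk mapping under natural, irrigated and composite scenarios
#'
#' Runs [run_location()] for every cell twice — natural rainfall and the
#' irrigation scenario — and builds the composite layer by the per-cell
#' rule: inside irrigated areas (mask `TRUE`) the irrigated-scenario EI
#' is mapped, elsewhere the natural-rainfall EI.
#'
#' @param sites list of [location_climate()] objects (one per cell), or
#'   a `climate_grid` from [make_grid()] (which carries its own mask and
#'   dimensions).
#' @param p a [climex_params()] object.
#' @param mask logical vector, one entry per cell; ignored (taken from
#'   the grid) when `sites` is a `climate_grid`.
#' @param scen the irrigation scenario for the irrigated layer.
#' @param nrow,ncol grid dimensions (defaulting to one row).
#' @inheritParams run_location
#' @return A `risk_grid` data frame: `cell`, `row`, `col`, `site_id`,
#'   `lat`, `lon`, `ei_natural`, `ei_irrigated`, `irrigated_mask`,
#'   `ei_composite`, with `nrow`/`ncol` attributes.
#' @export
run_grid <- function(sites, p, mask = NULL, scen = irrigation_scenario(),
                     nrow = NULL, ncol = NULL, hydro = hydro_defaults()) {
  if (inherits(sites, "climate_grid")) {
    if (is.null(mask)) mask <- sites$mask
    nrow <- sites$nrow
    ncol <- sites$ncol
    sites <- sites$sites
  }
  n <- length(sites)
  if (n == 0) stop("empty grid: no cells to run", call. = FALSE)
  if (is.null(nrow)) nrow <- 1L
  if (is.null(ncol)) ncol <- as.integer(ceiling(n / nrow))
  if (is.null(mask)) mask <- rep(FALSE, n)
  if (length(mask) != n) {
    stop("irrigation mask length (", length(mask),
         ") does not match cell count (", n, ")", call. = FALSE)
  }
  nat <- vapply(sites, function(s) run_location(s, p, NULL, hydro)$ei,
                numeric(1))
  irr <- vapply(sites, function(s) run_location(s, p, scen, hydro)$ei,
                numeric(1))
  cell <- seq_len(n)
  out <- data.frame(
    cell = cell,
    row = ((cell - 1L) %/% ncol) + 1L,
    col = ((cell - 1L) %% ncol) + 1L,
    site_id = vapply(sites, function(s) s$site_id, character(1)),
    lat = vapply(sites, function(s) s$lat, numeric(1)),
    lon = vapply(sites, function(s) s$lon, numeric(1)),
    ei_natural = nat,
    ei_irrigated = irr,
    irrigated_mask = as.logical(mask),
    stringsAsFactors = FALSE
  )
  out$ei_composite <- ifelse(out$irrigated_mask, out$ei_irrigated,
                             out$ei_natural)
  rownames(out) <- NULL
  structure(out, nrow = nrow, ncol = ncol,
            class = c("risk_grid", "data.frame"))
}

#' Weekly phenology table under natural and irrigated scenarios
#'
#' The weekly index trajectories used to compare modelled seasonality
#' with field observations: temperature index, and the moisture and
#' growth indices under both the natural-rainfall and irrigation
#' scenarios.
#'
#' @inheritParams run_location
#' @param scen the irrigation scenario for the irrigated columns.
#' @return A data frame with columns `week`, `ti`, `mi_natural`,
#'   `mi_irrigated`, `gi_natural`, `gi_irrigated` (52 rows).
#' @export
phenology <- function(clim, p, scen = irrigation_scenario(),
                      hydro = hydro_defaults()) {
  nat <- run_location(clim, p, NULL, hydro)$weekly
  irr <- run_location(clim, p, scen, hydro)$weekly
  data.frame(week = 1:52, ti = nat$ti,
             mi_natural = nat$mi, mi_irrigated = irr$mi,
             gi_natural = nat$gi, gi_irrigated = irr$gi)
}

#' Read / write risk-grid and phenology tables
#'
#' Plain CSV, one row per cell (or week); the write/read round trip is
#' exact for the grid structure and preserves the composite rule.
#'
#' @param grid a `risk_grid` from [run_grid()].
#' @param path CSV file path.
#' @export
write_risk_grid <- function(grid, path) {
  stopifnot(inherits(grid, "risk_grid"))
  if (nrow(grid) == 0) stop("empty grid: nothing to write", call. = FALSE)
  df <- as.data.frame(grid)
  df$grid_nrow <- attr(grid, "nrow")
  df$grid_ncol <- attr(grid, "ncol")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_risk_grid
#' @export
read_risk_grid <- function(path) {
  if (!file.exists(path)) stop("risk-grid file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nr <- df$grid_nrow[1]
  nc <- df$grid_ncol[1]
  df$grid_nrow <- NULL
  df$grid_ncol <- NULL
  df$site_id <- as.character(df$site_id)
  structure(df, nrow = nr, ncol = nc, class = c("risk_grid", "data.frame"))
}

#' @param phen a phenology table from [phenology()].
#' @rdname write_risk_grid
#' @export
write_phenology <- function(phen, path) {
  stopifnot(is.data.frame(phen), nrow(phen) == 52)
  utils::write.csv(phen, path, row.names = FALSE)
  invisible(path)
}
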