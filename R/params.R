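#' Model parameter sets
#'
#' A `climex_params` object holds every threshold and rate used by the
#' weekly growth indices, the annual stress indices and the degree-day
#' generation gate:
#'
#' * `DV0 <= DV1 <= DV2 <= DV3` — temperature response thresholds (deg C):
#'   development is zero at or below `DV0`, optimal on `[DV1, DV2]`, zero
#'   at or above `DV3`.
#' * `SM0 <= SM1 <= SM2 <= SM3` — soil-moisture response thresholds,
#'   dimensionless units of a 100 mm single-bucket soil moisture model
#'   (0 = oven dry, 1 = field capacity).
#' * Cold stress: `DTCS` (deg C-days/week; stress accumulates when weekly
#'   degree-days above `DVCS` fall below this), `DHCS` (rate, per week,
#'   stored negative as published), `DVCS` (deg C).
#' * Heat stress: `TTHS` (deg C), `THHS` (rate, per week).
#' * Dry stress: `SMDS` (soil-moisture threshold), `HDS` (rate, negative).
#' * Wet stress: `SMWS` (threshold), `HWS` (rate); a zero rate disables
#'   the mechanism entirely.
#' * Hot-wet stress: `TTHW` (deg C), `MTHW` (moisture threshold), `PHW`
#'   (rate); joint condition, zero rate disables.
#' * `PDD` — annual degree-days above `DV0` needed to complete one
#'   generation; locations below it are unsuitable regardless of growth.
#'
#' Rates are stored with their published sign (`DHCS`, `HDS` negative);
#' the stress engine uses absolute values for accumulation magnitude.
#'
#' @param ... named numeric scalars, one per symbol listed above, plus an
#'   optional `name` character scalar identifying the set.
#' @return A validated `climex_params` object (a named list).
#' @seealso [preset_params()], [read_params()], [write_params()]
#' @export
#' @examples
#' p <- preset_params("current")
#' p$DV0
climex_params <- function(...) {
  x <- list(...)
  nm <- x$name %||% "unnamed"
  x$name <- NULL
  missing <- setdiff(PARAM_KEYS, names(x))
  if (length(missing) > 0) {
    stop("missing parameter key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(x), PARAM_KEYS)
  if (length(extra) > 0) {
    stop("unknown parameter key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  x <- lapply(x[PARAM_KEYS], as.numeric)
  p <- structure(x, name = nm, class = "climex_params")
  validate_params(p)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

PARAM_KEYS <- c(
  "DV0", "DV1", "DV2", "DV3",
  "SM0", "SM1", "SM2", "SM3",
  "DTCS", "DHCS", "DVCS",
  "TTHS", "THHS",
  "SMDS", "HDS",
  "SMWS", "HWS",
  "TTHW", "MTHW", "PHW",
  "PDD"
)

validate_params <- function(p) {
  for (k in PARAM_KEYS) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("parameter ", k, " must be a single finite number", call. = FALSE)
    }
  }
  tv <- unlist(p[c("DV0", "DV1", "DV2", "DV3")])
  if (is.unsorted(tv)) {
    stop("temperature thresholds must satisfy DV0 <= DV1 <= DV2 <= DV3",
         call. = FALSE)
  }
  sv <- unlist(p[c("SM0", "SM1", "SM2", "SM3")])
  if (is.unsorted(sv)) {
    stop("moisture thresholds must satisfy SM0 <= SM1 <= SM2 <= SM3",
         call. = FALSE)
  }
  if (p$PDD < 0) stop("PDD must be non-negative", call. = FALSE)
  invisible(p)
}

# The four published parameter columns, transcribed verbatim.
.PRESETS <- list(
  spradbery_maywald = list(
    DV0 = 10, DV1 = 18, DV2 = 26, DV3 = 33,
    SM0 = 0, SM1 = 0.6, SM2 = 1.5, SM3 = 2.5,
    DTCS = 10, DHCS = -0.00014, DVCS = 10,
    TTHS = 31, THHS = 0.0035,
    SMDS = 0.2, HDS = -0.006,
    SMWS = 2.5, HWS = 0.002,
    TTHW = 26, MTHW = 0.8, PHW = 0.03,
    PDD = 350
  ),
  tribe_richardson = list(
    DV0 = 10, DV1 = 18, DV2 = 26, DV3 = 31,
    SM0 = 0.2, SM1 = 0.8, SM2 = 2, SM3 = 3,
    DTCS = 10, DHCS = -0.00014, DVCS = 10,
    TTHS = 30, THHS = 0.005,
    SMDS = 0.2, HDS = -0.01,
    SMWS = 3, HWS = 0.002,
    TTHW = 0, MTHW = 0, PHW = 0,   # hot-wet stress not included
    PDD = 350
  ),
  sutherst = list(
    DV0 = 10, DV1 = 18, DV2 = 26, DV3 = 31,
    SM0 = 0.2, SM1 = 0.6, SM2 = 1.5, SM3 = 2.5,
    DTCS = 10, DHCS = -0.00014, DVCS = 10,
    TTHS = 31, THHS = 0.0035,
    SMDS = 0.15, HDS = -0.008,
    SMWS = 2.5, HWS = 0.002,
    TTHW = 26, MTHW = 0.8, PHW = 0.03,
    PDD = 350
  ),
  current = list(
    DV0 = 6.5, DV1 = 18, DV2 = 26, DV3 = 33,
    SM0 = 0.2, SM1 = 0.6, SM2 = 1.5, SM3 = 2.5,
    DTCS = 10, DHCS = -0.00016, DVCS = 6.5,
    TTHS = 33, THHS = 0.0035,
    SMDS = 0.2, HDS = -0.008,
    SMWS = 0, HWS = 0,             # wet stress not included
    TTHW = 22, MTHW = 0.4, PHW = 0.009,
    PDD = 350
  )
)

#' Published parameter presets for the European wasp
#'
#' Returns one of the four published parameter sets fitted for
#' *Vespula germanica*: the two historical models
#' (`"spradbery_maywald"`, `"tribe_richardson"`), the unpublished update
#' (`"sutherst"`), and the irrigation-aware refit (`"current"`). In the
#' `tribe_richardson` set the hot-wet mechanism is disabled (all three
#' parameters zero); in the `current` set wet stress is disabled
#' (threshold and rate zero).
#'
#' @param name one of `"spradbery_maywald"`, `"tribe_richardson"`,
#'   `"sutherst"`, `"current"`.
#' @return A [climex_params()] object.
#' @export
#' @examples
#' preset_params("current")$DV0   # 6.5
preset_params <- function(name) {
  if (!is.character(name) || length(name) != 1 ||
      !(name %in% names(.PRESETS))) {
    stop("unknown preset ", deparse(substitute(name)), "; valid presets: ",
         paste(names(.PRESETS), collapse = ", "), call. = FALSE)
  }
  do.call(climex_params, c(.PRESETS[[name]], list(name = name)))
}

#' Read / write a parameter file
#'
#' The on-disk format is a flat YAML mapping with exactly the 21 symbol
#' keys (`DV0` .. `PDD`) plus a `name` field. Missing or unknown keys and
#' ordering violations are rejected; there are no silent defaults.
#'
#' @param path file path.
#' @return `read_params()` returns a [climex_params()] object;
#'   `write_params()` invisibly returns `path`.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  x <- yaml::read_yaml(path)
  if (!is.list(x)) stop("parameter file must be a flat key: value mapping",
                        call. = FALSE)
  do.call(climex_params, x)
}

#' @param p a [climex_params()] object.
#' @rdname read_params
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "climex_params"))
  out <- c(list(name = attr(p, "name")), unclass(p))
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

#' @export
print.climex_params <- function(x, ...) {
  cat("<climex_params> preset:", attr(x, "name"), "\n")
  v <- unlist(unclass(x))
  cat("  temperature (DV0..DV3): ", paste(v[1:4], collapse = ", "), "\n")
  cat("  moisture    (SM0..SM3): ", paste(v[5:8], collapse = ", "), "\n")
  cat("  cold stress  DTCS=", v["DTCS"], " DHCS=", v["DHCS"],
      " DVCS=", v["DVCS"], "\n", sep = "")
  cat("  heat stress  TTHS=", v["TTHS"], " THHS=", v["THHS"], "\n", sep = "")
  cat("  dry stress   SMDS=", v["SMDS"], " HDS=", v["HDS"], "\n", sep = "")
  cat("  wet stress   SMWS=", v["SMWS"], " HWS=", v["HWS"], "\n", sep = "")
  cat("  hot-wet      TTHW=", v["TTHW"], " MTHW=", v["MTHW"],
      " PHW=", v["PHW"], "\n", sep = "")
  cat("  generation   PDD=", v["PDD"], " degree-days\n", sep = "")
  invisible(x)
}
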